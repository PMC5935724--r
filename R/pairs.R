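#' Canonical key for an unordered variable pair
#'
#' Every unordered pair of variables is identified by a single key so that
#' edge tables, truth records and selections can be joined regardless of the
#' order in which the two endpoints were given. The canonical form sorts the
#' two identifiers lexicographically (C collation, so keys are stable across
#' locales) and joins them with `"|"`.
#'
#' @param a,b Character vectors of variable identifiers (recycled to a common
#'   length). `a[i]` must differ from `b[i]`.
#' @return Character vector of canonical pair keys.
#' @examples
#' pair_key("TG", "gene_03")
#' pair_key("gene_03", "TG")  # identical key
#' @export
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (any(a == b)) {
    stop("a variable cannot be paired with itself: ",
         paste(unique(a[a == b]), collapse = ", "))
  }
  first <- ifelse(cmp_lt(a, b), a, b)
  second <- ifelse(cmp_lt(a, b), b, a)
  paste(first, second, sep = "|")
}

# locale-independent a < b
cmp_lt <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  a < b
}

#' Enumerate all unordered pairs of a variable set
#'
#' Pairs are returned in upper-triangle order of the given variable vector
#' (the order used by correlation matrices), with canonically ordered
#' endpoint columns and a `pair` key column.
#'
#' @param variable_ids Character vector of distinct variable identifiers.
#' @return A data.frame with columns `var_a`, `var_b` (canonical order) and
#'   `pair`.
#' @export
all_pairs <- function(variable_ids) {
  variable_ids <- as.character(variable_ids)
  if (anyDuplicated(variable_ids)) stop("duplicated variable ids")
  if (length(variable_ids) < 2L) {
    return(data.frame(var_a = character(), var_b = character(),
                      pair = character(), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(length(variable_ids), 2L)
  x <- variable_ids[idx[1L, ]]
  y <- variable_ids[idx[2L, ]]
  swap <- !cmp_lt(x, y)
  a <- ifelse(swap, y, x)
  b <- ifelse(swap, x, y)
  data.frame(var_a = a, var_b = b, pair = paste(a, b, sep = "|"),
             stringsAsFactors = FALSE)
}
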
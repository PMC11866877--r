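#' Aggregated counts for binary matched pairs with missing single observations
#'
#' A `paired_table` holds the eight observable cell counts of the 3 x 3
#' frequency table for a matched-pairs design in which each patient receives
#' two interventions and either outcome (but never both) may be missing:
#' the four complete-pair cells `n00`, `n01`, `n10`, `n11` (first index is the
#' outcome under intervention 1, second under intervention 2), the counts
#' `n0x`, `n1x` of pairs with the second outcome missing, and `nx0`, `nx1`
#' with the first outcome missing. Patients with both outcomes missing
#' contribute no information and are not representable.
#'
#' @param n00,n01,n10,n11 Nonnegative counts of complete pairs; `nij` is the
#'   number of patients with outcome `i` under intervention 1 and `j` under
#'   intervention 2.
#' @param n0x,n1x Counts of pairs with the intervention-2 outcome missing.
#' @param nx0,nx1 Counts of pairs with the intervention-1 outcome missing.
#' @return An object of class `paired_table`: a named list of the eight cell
#'   counts with derived totals `npp` (complete pairs), `npx`, `nxp` and `n`.
#' @examples
#' tab <- paired_table(n00 = 40, n01 = 10, n10 = 20, n11 = 30,
#'                     n1x = 5, nx1 = 3)
#' tab
#' theta_complete(tab)
#' @export
paired_table <- function(n00 = 0, n01 = 0, n10 = 0, n11 = 0,
                         n0x = 0, n1x = 0, nx0 = 0, nx1 = 0) {
  cells <- c(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
             n0x = n0x, n1x = n1x, nx0 = nx0, nx1 = nx1)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("all cell counts must be nonnegative numbers")
  }
  if (any(cells != round(cells))) {
    stop("cell counts must be whole numbers")
  }
  x <- as.list(cells)
  x$npp <- n00 + n01 + n10 + n11
  x$npx <- n0x + n1x
  x$nxp <- nx0 + nx1
  x$n <- x$npp + x$npx + x$nxp
  structure(x, class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  m <- matrix(c(x$n00, x$n01, x$n0x,
                x$n10, x$n11, x$n1x,
                x$nx0, x$nx1, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(y1 = c("0", "1", "x"), y2 = c("0", "1", "x")))
  cat("Binary matched-pairs table (", x$n, " patients, ",
      x$npp, " complete pairs)\n", sep = "")
  print(m)
  invisible(x)
}

#' Tabulate pair-level outcomes into a `paired_table`
#'
#' @param y1,y2 Vectors of outcomes (0, 1 or `NA` for missing) under
#'   interventions 1 and 2; recycled to equal length is not supported, they
#'   must have the same length.
#' @param id Optional record identifiers used in error messages.
#' @param strict If `TRUE` (default), a pair with both outcomes missing is an
#'   error naming the offending record; if `FALSE`, such pairs are counted,
#'   dropped and reported via a warning.
#' @return A [paired_table]. With `strict = FALSE` the number of dropped
#'   doubly-missing records is attached as attribute `"n_dropped"`.
#' @export
tabulate_pairs <- function(y1, y2, id = NULL, strict = TRUE) {
  if (length(y1) != length(y2)) stop("y1 and y2 must have the same length")
  if (is.null(id)) id <- seq_along(y1)
  ok_val <- function(y) all(is.na(y) | y %in% c(0, 1))
  if (!ok_val(y1) || !ok_val(y2)) {
    stop("outcomes must be 0, 1 or missing (NA)")
  }
  both <- is.na(y1) & is.na(y2)
  if (any(both)) {
    if (strict) {
      stop("pair(s) with both outcomes missing: record ",
           paste(utils::head(id[both], 5L), collapse = ", "),
           if (sum(both) > 5L) " ..." else "")
    }
    warning(sum(both), " pair(s) with both outcomes missing were dropped")
    y1 <- y1[!both]; y2 <- y2[!both]
  }
  tab <- paired_table(
    n00 = sum(!is.na(y1) & !is.na(y2) & y1 == 0 & y2 == 0),
    n01 = sum(!is.na(y1) & !is.na(y2) & y1 == 0 & y2 == 1),
    n10 = sum(!is.na(y1) & !is.na(y2) & y1 == 1 & y2 == 0),
    n11 = sum(!is.na(y1) & !is.na(y2) & y1 == 1 & y2 == 1),
    n0x = sum(!is.na(y1) & is.na(y2) & y1 == 0),
    n1x = sum(!is.na(y1) & is.na(y2) & y1 == 1),
    nx0 = sum(is.na(y1) & !is.na(y2) & y2 == 0),
    nx1 = sum(is.na(y1) & !is.na(y2) & y2 == 1))
  if (any(both)) attr(tab, "n_dropped") <- sum(both)
  tab
}

#' Expand a `paired_table` back to pair-level records
#'
#' Inverse of [tabulate_pairs] up to record order: returns one row per
#' patient with outcomes 0, 1 or `NA`.
#'
#' @param table A [paired_table].
#' @return A data frame with columns `id`, `y1`, `y2`.
#' @export
expand_pairs <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  y1 <- c(rep(0, table$n00), rep(0, table$n01), rep(1, table$n10),
          rep(1, table$n11), rep(0, table$n0x), rep(1, table$n1x),
          rep(NA, table$nx0), rep(NA, table$nx1))
  y2 <- c(rep(0, table$n00), rep(1, table$n01), rep(0, table$n10),
          rep(1, table$n11), rep(NA, table$n0x), rep(NA, table$n1x),
          rep(0, table$nx0), rep(1, table$nx1))
  data.frame(id = seq_along(y1), y1 = y1, y2 = y2)
}

#' Risk-difference point estimates
#'
#' `theta_complete()` is the complete-case estimator
#' `(n10 - n01) / npp`, using completely observed pairs only.
#' `theta_all_observed()` uses every observed outcome,
#' `(n10 + n11 + n1x) / (npp + npx) - (n01 + n11 + nx1) / (npp + nxp)`;
#' it is unbiased under MAR missingness. The two coincide when no
#' observation is missing.
#'
#' @param table A [paired_table].
#' @return An object of class `risk_difference`: a list with elements
#'   `estimate` (in `[-1, 1]`) and `basis` (`"complete_cases"` or
#'   `"all_observed"`).
#' @export
theta_complete <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  if (table$npp == 0) {
    stop("risk difference undefined: no completely observed pairs")
  }
  structure(list(estimate = (table$n10 - table$n01) / table$npp,
                 basis = "complete_cases", n_used = table$npp),
            class = "risk_difference")
}

#' @rdname theta_complete
#' @export
theta_all_observed <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  d1 <- table$npp + table$npx
  d2 <- table$npp + table$nxp
  if (d1 == 0 || d2 == 0) {
    stop("risk difference undefined: no observed outcomes in one arm")
  }
  est <- (table$n10 + table$n11 + table$n1x) / d1 -
    (table$n01 + table$n11 + table$nx1) / d2
  structure(list(estimate = est, basis = "all_observed",
                 n_used = table$n),
            class = "risk_difference")
}

#' @export
print.risk_difference <- function(x, ...) {
  cat(sprintf("Risk difference (%s): %.6f  [n used: %d]\n",
              x$basis, x$estimate, x$n_used))
  invisible(x)
}

#' @export
as.double.risk_difference <- function(x, ...) x$estimate

# --- file interfaces ---------------------------------------------------------

detect_sep <- function(file) {
  first <- readLines(file, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read and write pair-level data
#'
#' Pair-level files are comma- or tab-delimited with a required header and
#' columns `id`, `y1`, `y2`. Missing outcomes may be coded as an empty field,
#' `NA` or `x`.
#'
#' @param file Path to a delimited text file.
#' @param strict Passed to [tabulate_pairs] semantics: if `TRUE`, records
#'   with both outcomes missing are an error.
#' @return `read_pairs()`: a data frame with columns `id`, `y1`, `y2` where
#'   missing outcomes are `NA`.
#' @export
read_pairs <- function(file, strict = TRUE) {
  sep <- detect_sep(file)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("id", "y1", "y2")
  if (!all(need %in% names(df))) {
    stop("pair-level file must have header columns id, y1, y2")
  }
  decode <- function(v) {
    v[v %in% c("", "NA", "x", "X")] <- NA_character_
    out <- suppressWarnings(as.integer(v))
    if (any(!is.na(v) & (is.na(out) | !(out %in% c(0L, 1L))))) {
      stop("outcomes must be 0, 1, or one of '', NA, x for missing")
    }
    out
  }
  y1 <- decode(df$y1); y2 <- decode(df$y2)
  both <- is.na(y1) & is.na(y2)
  if (any(both)) {
    if (strict) {
      stop("record(s) with both outcomes missing: id ",
           paste(utils::head(df$id[both], 5L), collapse = ", "))
    }
    warning(sum(both), " record(s) with both outcomes missing were dropped")
  }
  data.frame(id = df$id[!both], y1 = y1[!both], y2 = y2[!both],
             stringsAsFactors = FALSE)
}

#' @rdname read_pairs
#' @param pairs Data frame with columns `id`, `y1`, `y2`.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @export
write_pairs <- function(pairs, file, sep = ",") {
  stopifnot(all(c("id", "y1", "y2") %in% names(pairs)))
  utils::write.table(pairs[c("id", "y1", "y2")], file, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}

#' Read and write aggregated paired-count tables
#'
#' Table files are delimited text with a header naming the eight cells
#' `n00,n01,n10,n11,n0x,n1x,nx0,nx1` and a single row of counts.
#'
#' @param file Path to a delimited text file.
#' @return `read_paired_table()`: a [paired_table].
#' @export
read_paired_table <- function(file) {
  sep <- detect_sep(file)
  df <- utils::read.table(file, header = TRUE, sep = sep)
  need <- c("n00", "n01", "n10", "n11", "n0x", "n1x", "nx0", "nx1")
  missing_cols <- setdiff(need, names(df))
  for (m in missing_cols) df[[m]] <- 0
  if (nrow(df) != 1L) stop("table file must contain exactly one row of counts")
  do.call(paired_table, as.list(df[1L, need]))
}

#' @rdname read_paired_table
#' @param table A [paired_table].
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @export
write_paired_table <- function(table, file, sep = ",") {
  stopifnot(inherits(table, "paired_table"))
  cells <- table[c("n00", "n01", "n10", "n11", "n0x", "n1x", "nx0", "nx1")]
  utils::write.table(as.data.frame(cells), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Internal fast constructor for counts that are valid by construction
# (simulation hot path); skips the validation of paired_table().
new_ptab <- function(n00, n01, n10, n11, n0x = 0, n1x = 0, nx0 = 0, nx1 = 0) {
  npp <- n00 + n01 + n10 + n11
  npx <- n0x + n1x
  nxp <- nx0 + nx1
  structure(list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
                 n0x = n0x, n1x = n1x, nx0 = nx0, nx1 = nx1,
                 npp = npp, npx = npx, nxp = nxp, n = npp + npx + nxp),
            class = "paired_table")
}

# Internal: coerce pairs data frame or paired_table to paired_table.
as_paired_table <- function(x, strict = TRUE) {
  if (inherits(x, "paired_table")) return(x)
  if (is.data.frame(x) && all(c("y1", "y2") %in% names(x))) {
    return(tabulate_pairs(x$y1, x$y2, id = x$id %||% NULL, strict = strict))
  }
  stop("expected a paired_table or a data frame with columns y1, y2")
}
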
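#' Load a TRX dinucleotide flexibility table
#'
#' TRX scores quantify, per dinucleotide step, the percentage frequency
#' with which the step and its reverse complement adopt the BII phosphate
#' conformation in NMR data; higher scores mean more flexible DNA. A
#' table therefore has 10 free values (6 complement pairs + 4
#' self-complementary steps); this reader accepts a two-column TSV
#' (`dinucleotide`, `score`) with 10-16 rows, expands it to all 16 keys,
#' and enforces complement symmetry: a missing class is an error naming
#' it, and two entries of one complement class with different values are
#' rejected.
#'
#' The table shipped with the package
#' (`system.file("extdata", "trx_table_synthetic.tsv", package =
#' "transpoloop")`) is a synthetic stand-in with the documented structure
#' and plausible relative ordering, not measured values; analyses of real
#' sequence data should substitute the published NMR-derived scale.
#'
#' @param path TSV path; default loads the synthetic stand-in table.
#' @return Named numeric vector of length 16 (class `trx_table`).
#' @export
load_trx_table <- function(path = system.file("extdata",
                                              "trx_table_synthetic.tsv",
                                              package = "transpoloop")) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "score") %in% names(raw)))
    stop("TRX table needs columns 'dinucleotide' and 'score'")
  trx_table(setNames(raw$score, toupper(raw$dinucleotide)))
}

revcomp_dinuc <- function(d) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(d, ""), function(ch) paste0(comp[ch[2]], comp[ch[1]]), "")
}

#' @rdname load_trx_table
#' @param scores Named numeric vector over dinucleotides (>= the 10
#'   complement classes; scores must be non-negative).
#' @export
trx_table <- function(scores) {
  bases <- c("A", "C", "G", "T")
  dn <- as.vector(outer(bases, bases, paste0))
  bad <- setdiff(names(scores), dn)
  if (length(bad)) stop("unknown dinucleotide(s): ", paste(bad, collapse = ", "))
  if (any(scores < 0)) stop("TRX scores are percent frequencies; must be >= 0")
  full <- setNames(rep(NA_real_, 16), dn)
  for (d in names(scores)) {
    rc <- revcomp_dinuc(d)
    for (key in unique(c(d, rc))) {
      if (!is.na(full[key]) && full[key] != scores[[d]])
        stop("complement asymmetry: ", key, " given ", full[key],
             " but its class partner gives ", scores[[d]])
      full[key] <- scores[[d]]
    }
  }
  missing <- names(full)[is.na(full)]
  if (length(missing))
    stop("missing dinucleotide class(es): ", paste(missing, collapse = ", "))
  structure(full, class = "trx_table")
}

#' @rdname load_trx_table
#' @param table A `trx_table`.
#' @param path Output TSV path.
#' @export
write_trx_table <- function(table, path) {
  df <- data.frame(dinucleotide = names(table), score = as.numeric(table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean TRX score of a sequence
#'
#' Average of the table values over all consecutive dinucleotide steps of
#' the sequence. Steps containing a non-ACGT symbol (e.g. N) are skipped.
#' Because the table is complement-symmetric, a sequence and its reverse
#' complement score identically.
#'
#' @param seq A character string, `DNAString`, or anything coercible by
#'   `as.character` (length >= 2).
#' @param table A `trx_table` (default: the shipped synthetic table).
#' @return List with `score` (mean, `NA` if no step is scorable) and
#'   `n_steps` (number of scored steps).
#' @examples
#' toy <- trx_table(c(AA = 10, AT = 20, AC = 5, AG = 5, CA = 5, CC = 5,
#'                    CG = 5, GA = 5, GC = 5, TA = 5))
#' sequence_trx("AAT", toy)  # mean of AA (10) and AT (20) = 15
#' @export
sequence_trx <- function(seq, table = load_trx_table()) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 2) stop("sequence must have length >= 2")
  ch <- strsplit(s, "")[[1]]
  steps <- paste0(ch[-length(ch)], ch[-1])
  v <- unclass(table)[steps]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("no scorable dinucleotide step; score undefined")
    return(list(score = NA_real_, n_steps = 0L))
  }
  list(score = mean(v), n_steps = length(v))
}

#' Per-region TRX scores
#'
#' Scores genomic intervals against sequences: per-interval
#' [sequence_trx()] over the subsequence, or whole sequences when
#' `intervals` is `NULL` ("genome-wide" mode). Intervals are 0-based
#' half-open; an interval outside its sequence is an error naming it.
#'
#' @param sequences A named `DNAStringSet` (or named character vector).
#' @param intervals `NULL`, or a tibble `chrom`, `start`, `end` with an
#'   optional `subfamily` label column.
#' @param table A `trx_table`.
#' @return Tibble with `chrom`, `start`, `end`, optional `subfamily`,
#'   `trx` and `n_steps` (one row per interval or per sequence).
#' @export
region_trx <- function(sequences, intervals = NULL, table = load_trx_table()) {
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)))
    stop("sequences must be named")
  if (is.null(intervals)) {
    intervals <- tibble::tibble(chrom = names(sequences), start = 0,
                                end = Biostrings::width(sequences))
  }
  bad <- !intervals$chrom %in% names(sequences)
  if (any(bad))
    stop("unknown sequence for interval(s): ",
         paste(unique(intervals$chrom[bad]), collapse = ", "))
  widths <- Biostrings::width(sequences)[match(intervals$chrom,
                                               names(sequences))]
  oob <- intervals$start < 0 | intervals$end > widths |
    intervals$start >= intervals$end
  if (any(oob)) {
    i <- which(oob)[1]
    stop("interval out of bounds: ", intervals$chrom[i], ":",
         intervals$start[i], "-", intervals$end[i])
  }
  res <- purrr::map(seq_len(nrow(intervals)), function(i) {
    s <- Biostrings::subseq(sequences[[intervals$chrom[i]]],
                            start = intervals$start[i] + 1,
                            end = intervals$end[i])
    suppressWarnings(sequence_trx(s, table))
  })
  out <- intervals
  out$trx <- vapply(res, `[[`, 0, "score")
  out$n_steps <- vapply(res, `[[`, 0L, "n_steps")
  tibble::as_tibble(out)
}

#' Per-label mean TRX scores
#'
#' Aggregates [region_trx()] records per subfamily label, averaging the
#' per-element scores (each element counts once, regardless of length);
#' `pooled = TRUE` instead pools all scored steps, weighting elements by
#' their number of steps.
#'
#' @param records A [region_trx()] tibble with a `subfamily` column.
#' @param pooled Step-pooled instead of per-element averaging.
#' @return Tibble `subfamily`, `n_elements`, `trx_mean`.
#' @export
subfamily_trx <- function(records, pooled = FALSE) {
  stopifnot("subfamily" %in% names(records))
  records |>
    dplyr::filter(is.finite(.data$trx)) |>
    dplyr::group_by(.data$subfamily) |>
    dplyr::summarise(
      n_elements = dplyr::n(),
      trx_mean = if (pooled)
        sum(.data$trx * .data$n_steps) / sum(.data$n_steps)
      else mean(.data$trx),
      .groups = "drop")
}

#' Flexibility-accessibility regression
#'
#' Ordinary least squares of per-subfamily open-chromatin overlap (or
#' in-cluster accessibility) fractions on per-subfamily mean TRX scores,
#' with the standard t-test on the slope.
#'
#' @param data Tibble with one row per subfamily.
#' @param trx_col,frac_col Column names (defaults `trx_mean`,
#'   `fraction`).
#' @return Object of class `trx_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `n` and the underlying `lm` in `fit`.
#'   Supports [tidy()] and [glance()].
#' @export
flexibility_accessibility_fit <- function(data, trx_col = "trx_mean",
                                          frac_col = "fraction") {
  x <- data[[trx_col]]; y <- data[[frac_col]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 subfamilies")
  if (var(x) == 0) stop("zero variance in TRX scores; slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = coef(fit)[["x"]], intercept = coef(fit)[["(Intercept)"]],
                 r_squared = sm$r.squared,
                 p_slope = sm$coefficients["x", 4], n = length(x), fit = fit),
            class = "trx_fit")
}

#' @export
print.trx_fit <- function(x, ...) {
  cat("<trx_fit> slope =", signif(x$slope, 4), " R2 =",
      signif(x$r_squared, 3), " p_slope =", signif(x$p_slope, 3), "\n")
  invisible(x)
}

#' @rdname flexibility_accessibility_fit
#' @param x A `trx_fit`.
#' @param ... Unused.
#' @export
tidy.trx_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
                 p.value = unname(sm[, 4]))
}

#' @rdname flexibility_accessibility_fit
#' @export
glance.trx_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_slope = x$p_slope, n = x$n)
}

#' Flexibility-age trends per transposon family
#'
#' Per-family OLS of mean subfamily TRX score on chronological age rank
#' (rank 1 = youngest). Families with fewer than `min_members`
#' subfamilies are skipped with a warning. A negative slope means
#' flexibility falls with evolutionary age.
#'
#' @param data Tibble with columns `family`, `age_rank`, `trx_mean`.
#' @param min_members Minimum subfamilies per family (default 3).
#' @return Tibble `family`, `n`, `slope`, `se`, `r_squared`, `p_value`.
#' @export
age_trend_fit <- function(data, min_members = 3) {
  stopifnot(all(c("family", "age_rank", "trx_mean") %in% names(data)))
  counts <- table(data$family)
  small <- names(counts)[counts < min_members]
  if (length(small))
    warning("skipping family/families with < ", min_members, " members: ",
            paste(small, collapse = ", "))
  data |>
    dplyr::filter(!.data$family %in% small) |>
    dplyr::group_by(.data$family) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(trx_mean ~ age_rank, data = d)
      sm <- summary(fit)$coefficients
      tibble::tibble(n = nrow(d), slope = sm["age_rank", 1],
                     se = sm["age_rank", 2],
                     r_squared = summary(fit)$r.squared,
                     p_value = sm["age_rank", 4])
    }) |>
    dplyr::ungroup()
}
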
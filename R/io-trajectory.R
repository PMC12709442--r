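#' Write polymer configurations as extended XYZ
#'
#' One frame per state: an atom-count line, a comment line carrying the
#' elapsed timestep and transposed count, then one `type x y z` row per
#' particle with type letters `N` (native), `T` (transposed), `P`
#' (transposase). Positions are in reduced units (sigma).
#'
#' @param states A `polymer_state` or a list of them (frames).
#' @param path Output file.
#' @param append Append to an existing trajectory file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(states, path, append = FALSE) {
  if (inherits(states, "polymer_state")) states <- list(states)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (st in states) {
    n <- nrow(st$pos)
    writeLines(as.character(n), con)
    writeLines(sprintf("step=%d n_tr=%d", st$steps, sum(st$kind == 1L)), con)
    type <- c("N", "T", "P")[st$kind + 1L]
    writeLines(sprintf("%s %.6f %.6f %.6f", type,
                       st$pos[, 1], st$pos[, 2], st$pos[, 3]), con)
  }
  invisible(path)
}

#' Write an unfolding trace or insertion history as TSV
#'
#' @param x An `insertion_run` (both its trace and history are written,
#'   suffixed `_trace.tsv` / `_history.tsv`) or a data frame.
#' @param path Output file (for an `insertion_run`, the stem).
#' @return The path(s), invisibly.
#' @export
write_trace <- function(x, path) {
  tsv <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  if (inherits(x, "insertion_run")) {
    stem <- sub("\\.tsv$", "", path)
    paths <- paste0(stem, c("_trace.tsv", "_history.tsv"))
    tsv(x$trace, paths[1])
    tsv(x$history, paths[2])
    return(invisible(paths))
  }
  tsv(x, path)
  invisible(path)
}
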
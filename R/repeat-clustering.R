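#' Read repeat element annotations
#'
#' Reads BED3/BED6 or a RepeatMasker-style TSV (columns `genoName`,
#' `genoStart`, `genoEnd`, `repName`, header required) into the element
#' annotation tibble used throughout. Coordinates are 0-based half-open.
#' Rows with `start >= end` or non-numeric coordinates are rejected; the
#' rejected count is reported via a message.
#'
#' @param path File path.
#' @param format `"bed"` or `"rmsk_tsv"`.
#' @param subfamily_filter Optional character vector: keep only elements
#'   whose subfamily (BED name field / `repName`) matches.
#' @param exclude_chroms Optional character vector of chromosomes to drop
#'   (e.g. sex chromosomes when comparing against datasets that lack
#'   them); configuration, never hard-coded.
#' @return Tibble `chrom`, `start`, `end`, `subfamily`, `center`, sorted
#'   by (chrom, start).
#' @export
read_elements <- function(path, format = c("bed", "rmsk_tsv"),
                          subfamily_filter = NULL, exclude_chroms = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character",
                             col.names = paste0("V", 1:6), fill = TRUE,
                             comment.char = "#")
    el <- tibble::tibble(chrom = raw$V1,
                         start = suppressWarnings(as.numeric(raw$V2)),
                         end = suppressWarnings(as.numeric(raw$V3)),
                         subfamily = ifelse(is.na(raw$V4) | raw$V4 == "",
                                            ".", raw$V4))
  } else {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("genoName", "genoStart", "genoEnd", "repName")
    if (!all(need %in% names(raw)))
      stop("rmsk_tsv requires columns: ", paste(need, collapse = ", "))
    el <- tibble::tibble(chrom = as.character(raw$genoName),
                         start = suppressWarnings(as.numeric(raw$genoStart)),
                         end = suppressWarnings(as.numeric(raw$genoEnd)),
                         subfamily = as.character(raw$repName))
  }
  ok <- is.finite(el$start) & is.finite(el$end) & el$start < el$end
  if (any(!ok))
    message("rejected ", sum(!ok), " malformed line(s)")
  el <- el[ok, ]
  if (!is.null(exclude_chroms)) el <- el[!el$chrom %in% exclude_chroms, ]
  if (!is.null(subfamily_filter)) {
    el <- el[el$subfamily %in% subfamily_filter, ]
    if (nrow(el) == 0L)
      stop("no elements left after subfamily filter: ",
           paste(subfamily_filter, collapse = ", "))
  }
  add_centers(el) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Uniformly placed reference elements
#'
#' For each annotated element, places a reference element of the same
#' length at a position drawn uniformly over the genomic range covered by
#' the elements on its chromosome (per-chromosome span from the lowest
#' start to the highest end; set `per_chromosome = FALSE` to pool the
#' spans genome-wide and redistribute elements across chromosomes
#' proportionally to span).
#'
#' @param elements Element annotation tibble.
#' @param per_chromosome Keep each reference element on its source
#'   chromosome (default) or pool.
#' @param seed Optional seed.
#' @return Reference annotation tibble with subfamily `"reference"`.
#' @export
uniform_reference <- function(elements, per_chromosome = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- elements |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(lo = min(.data$start), hi = max(.data$end),
                     .groups = "drop")
  lens <- elements$end - elements$start
  if (per_chromosome) {
    i <- match(elements$chrom, span$chrom)
    chrom <- elements$chrom
  } else {
    i <- sample.int(nrow(span), nrow(elements), replace = TRUE,
                    prob = span$hi - span$lo)
    chrom <- span$chrom[i]
  }
  lo <- span$lo[i]; hi <- span$hi[i]
  start <- floor(lo + runif(nrow(elements)) * pmax(1, hi - lo - lens + 1))
  tibble::tibble(chrom = chrom, start = start, end = start + lens,
                 subfamily = "reference") |>
    add_centers() |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Within-chromosome pairwise center distances
#'
#' All unordered pairwise distances between element centers on the same
#' chromosome; pairs never cross chromosomes, so the total count is
#' `sum n_c (n_c - 1) / 2` over chromosomes `c`. Chromosomes with fewer
#' than two centers contribute nothing; if none has two, an empty result
#' is returned with a warning.
#'
#' @param elements Element annotation tibble (needs `chrom` and `center`;
#'   centers are derived from start/end if absent).
#' @return Tibble with columns `chrom` and `distance`.
#' @export
pairwise_distances <- function(elements) {
  if (!"center" %in% names(elements)) elements <- add_centers(elements)
  out <- elements |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::reframe(distance = as.numeric(stats::dist(.data$center)))
  if (nrow(out) == 0L)
    warning("fewer than 2 centers on every chromosome; no pairs")
  out
}

#' Genomic range covered by elements
#'
#' The length `L` entering the uniform pairwise-distance density: per
#' chromosome, the span from the lowest element start to the highest
#' element end; with `pooled = TRUE`, the single summed span over all
#' chromosomes.
#'
#' @param elements Element annotation tibble.
#' @param pooled Sum the per-chromosome spans into one genome-wide `L`.
#' @return A tibble `chrom`, `span`, or a single number when pooled.
#' @export
genomic_span <- function(elements, pooled = FALSE) {
  span <- elements |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(span = max(.data$end) - min(.data$start),
                     .groups = "drop")
  if (pooled) sum(span$span) else span
}

#' Pairwise-distance density under uniform placement
#'
#' For points placed independently and uniformly on a segment of length
#' `L`, the probability density of a pairwise distance `x` is
#' `p(x) = 2 (L - x) / L^2` on `[0, L]`.
#'
#' @param x Distances in `[0, L]` (vectorized).
#' @param L Genomic range length (> 0).
#' @return Density values.
#' @export
uniform_density <- function(x, L) {
  if (L <= 0) stop("L must be positive")
  if (any(x < 0 | x > L)) stop("x must lie in [0, L]")
  2 * (L - x) / L^2
}

#' Logarithmically binned distance histogram
#'
#' Histogram of pairwise distances with logarithmically spaced bin edges,
#' normalized to a probability density (`sum(density * width) == 1`).
#' Deviations from uniform placement occur mainly at short distances,
#' which log bins resolve. Zero distances (identical centers) are
#' assigned to the smallest bin, since log-spaced edges exclude zero.
#'
#' @param distances Positive distances (zeros tolerated, see above); a
#'   [pairwise_distances()] tibble is also accepted.
#' @param n_bins Number of bins.
#' @return Tibble `bin_lo`, `bin_hi`, `mid` (geometric midpoint),
#'   `count`, `density`.
#' @export
log_binned_histogram <- function(distances, n_bins = 40) {
  if (is.data.frame(distances)) distances <- distances$distance
  if (length(distances) == 0L) stop("empty distance set")
  pos <- distances[distances > 0]
  if (length(pos) == 0L) stop("all distances are zero")
  lo <- min(pos); hi <- max(pos)
  if (lo == hi) { lo <- lo * 0.99; hi <- hi * 1.01 }
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  edges[1] <- edges[1] * (1 - 1e-12); edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-12)
  idx <- findInterval(pmax(distances, lo), edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  cnt <- tabulate(idx, n_bins)
  w <- diff(edges)
  tibble::tibble(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                 mid = sqrt(edges[-(n_bins + 1)] * edges[-1]),
                 count = cnt, density = cnt / (length(distances) * w))
}

#' One-dimensional DBSCAN on element centers
#'
#' Density-based clustering of genomic coordinates with standard DBSCAN
#' semantics: a point is a core point when at least `min_samples` points
#' (itself included) lie within `eps`; clusters are the connected
#' components of core points within `eps` of each other, plus border
#' points within `eps` of a core; everything else is noise. For
#' `min_samples = 2` this equals the transitive closure of the
#' "within eps" relation with singletons as noise.
#'
#' @param centers Numeric coordinates (one chromosome).
#' @param eps Neighborhood radius in basepairs (default 10,000).
#' @param min_samples Minimum neighborhood size (default 2).
#' @return Integer cluster labels in input order: 0 for noise, clusters
#'   numbered 1, 2, ... by order of first occurrence along the
#'   coordinate.
#' @export
dbscan_1d <- function(centers, eps = 10000, min_samples = 2) {
  stopifnot(eps > 0, min_samples >= 2)
  n <- length(centers)
  if (n == 0L) return(integer(0))
  ord <- order(centers)
  x <- centers[ord]
  left <- findInterval(x - eps, x, left.open = TRUE)           # strictly below x - eps
  right <- findInterval(x + eps, x)
  n_neigh <- right - left                                      # includes self
  core <- n_neigh >= min_samples
  lab <- integer(n)
  cur <- 0L
  last_core <- -Inf; last_lab <- 0L
  for (i in seq_len(n)) {
    if (!core[i]) next
    if (x[i] - last_core <= eps) lab[i] <- last_lab
    else { cur <- cur + 1L; lab[i] <- cur }
    last_core <- x[i]; last_lab <- lab[i]
  }
  core_x <- x[core]; core_lab <- lab[core]
  if (length(core_x) > 0L) {
    for (i in which(!core & n_neigh > 1)) {
      j <- findInterval(x[i], core_x)
      best <- 0L; bestd <- Inf
      for (k in c(j, j + 1L)) {
        if (k >= 1L && k <= length(core_x)) {
          d <- abs(x[i] - core_x[k])
          if (d <= eps && d < bestd) { bestd <- d; best <- core_lab[k] }
        }
      }
      lab[i] <- best
    }
  }
  out <- integer(n)
  out[ord] <- lab
  out
}

#' Cluster elements per chromosome
#'
#' Runs [dbscan_1d()] on element centers independently per chromosome
#' (clusters never span chromosomes) and appends a `cluster` column:
#' `"<chrom>#<id>"` or `NA` for noise.
#'
#' @param elements Element annotation tibble.
#' @param eps,min_samples DBSCAN parameters (defaults 10,000 nt and 2).
#' @return The elements with `cluster` and `in_cluster` columns.
#' @export
cluster_elements <- function(elements, eps = 10000, min_samples = 2) {
  if (!"center" %in% names(elements)) elements <- add_centers(elements)
  elements |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.lab = dbscan_1d(.data$center, eps, min_samples)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      cluster = ifelse(.data$.lab > 0,
                       paste0(.data$chrom, "#", .data$.lab), NA_character_),
      in_cluster = !is.na(.data$cluster)) |>
    dplyr::select(-".lab")
}

#' Cluster summary statistics
#'
#' Per-chromosome fraction of elements in clusters, plus cluster count
#' and span statistics. A cluster's span runs from the minimum start to
#' the maximum end of its members (element lengths, not centers, set the
#' total cluster length). With no clusters the fraction is 0 and span
#' statistics are `NA`.
#'
#' @param elements Output of [cluster_elements()].
#' @return List with `per_chromosome` (tibble `chrom`, `n`, `n_clustered`,
#'   `fraction`), `clusters` (tibble `cluster`, `chrom`, `n_members`,
#'   `span_start`, `span_end`, `span`) and `summary` (tibble
#'   `n_clusters`, `mean_span`, `max_span`, `fraction_in_clusters`).
#' @export
cluster_stats <- function(elements) {
  stopifnot("cluster" %in% names(elements))
  per_chrom <- elements |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = dplyr::n(),
                     n_clustered = sum(.data$in_cluster),
                     fraction = mean(.data$in_cluster), .groups = "drop")
  clustered <- dplyr::filter(elements, .data$in_cluster)
  if (nrow(clustered) == 0L) {
    clusters <- tibble::tibble(cluster = character(0), chrom = character(0),
                               n_members = integer(0), span_start = numeric(0),
                               span_end = numeric(0), span = numeric(0))
  } else {
    clusters <- clustered |>
      dplyr::group_by(.data$cluster, .data$chrom) |>
      dplyr::summarise(n_members = dplyr::n(),
                       span_start = min(.data$start),
                       span_end = max(.data$end),
                       .groups = "drop") |>
      dplyr::mutate(span = .data$span_end - .data$span_start)
  }
  summary <- tibble::tibble(
    n_clusters = nrow(clusters),
    mean_span = if (nrow(clusters)) mean(clusters$span) else NA_real_,
    max_span = if (nrow(clusters)) max(clusters$span) else NA_real_,
    fraction_in_clusters = mean(elements$in_cluster))
  list(per_chromosome = per_chrom, clusters = clusters, summary = summary)
}

#' Filter open-chromatin peaks to a high-confidence subset
#'
#' Keeps peaks detected by both the DNaseI and FAIRE assays, or with a
#' combined p-value below `p_cutoff`.
#'
#' @param peaks Tibble with logical columns `flag_dnase` and `flag_faire`
#'   and/or a numeric `combined_p` column.
#' @param p_cutoff Combined p-value threshold (default 0.01).
#' @return The retained peaks.
#' @export
filter_peaks <- function(peaks, p_cutoff = 0.01) {
  has_flags <- all(c("flag_dnase", "flag_faire") %in% names(peaks))
  has_p <- "combined_p" %in% names(peaks)
  if (!has_flags && !has_p)
    stop("peaks need flag_dnase/flag_faire columns and/or a combined_p column")
  both <- if (has_flags) peaks$flag_dnase & peaks$flag_faire else FALSE
  sig <- if (has_p) peaks$combined_p < p_cutoff else FALSE
  peaks[both | sig, ]
}

# Internal: logical overlap indicator per element.
element_overlaps <- function(elements, open, mode) {
  ov <- logical(nrow(elements))
  for (ch in unique(elements$chrom)) {
    ei <- which(elements$chrom == ch)
    oi <- which(open$chrom == ch)
    if (length(oi) == 0L) next
    ir_open <- IRanges::IRanges(start = open$start[oi] + 1, end = open$end[oi])
    if (mode == "interval") {
      ir_el <- IRanges::IRanges(start = elements$start[ei] + 1,
                                end = elements$end[ei])
    } else {
      ctr <- elements$center[ei] + 1
      ir_el <- IRanges::IRanges(start = ctr, end = ctr)
    }
    ov[ei] <- IRanges::overlapsAny(ir_el, ir_open)
  }
  ov
}

#' Open-chromatin overlap fractions
#'
#' Fraction of elements overlapping open-chromatin intervals, per
#' chromosome, split by cluster membership when an `in_cluster` column is
#' present. In `"interval"` mode any basepair overlap counts; in
#' `"center"` mode the element's center must fall inside an open
#' interval.
#'
#' @param elements Element annotation tibble (optionally with
#'   `in_cluster` from [cluster_elements()]).
#' @param open Interval tibble `chrom`, `start`, `end`.
#' @param mode `"interval"` (default) or `"center"`.
#' @return Tibble with `chrom`, optional `in_cluster`, `n` and
#'   `fraction`.
#' @export
overlap_fraction <- function(elements, open, mode = c("interval", "center")) {
  mode <- match.arg(mode)
  if (!"center" %in% names(elements)) elements <- add_centers(elements)
  elements$.ov <- element_overlaps(elements, open, mode)
  keys <- c("chrom", intersect("in_cluster", names(elements)))
  elements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(), fraction = mean(.data$.ov),
                     .groups = "drop")
}

#' Compare two groups of per-chromosome fractions
#'
#' Two-sided Mann-Whitney U rank test (midranks for ties, normal
#' approximation with continuity correction). Used to compare
#' per-chromosome in-cluster or overlap fractions between annotated
#' elements and uniform references.
#'
#' @param a,b Numeric vectors (at least 3 values each).
#' @return The two-sided p-value.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per group")
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                correct = TRUE)$p.value)
}
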
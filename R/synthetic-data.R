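#' Define a synthetic genome
#'
#' A minimal genome skeleton for fixture generation: chromosome names and
#' sizes. Coordinates throughout the package are 0-based, half-open (BED
#' convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param size Integer sizes in basepairs (all positive).
#' @return A tibble with columns `chrom` and `size`.
#' @examples
#' synth_genome(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
synth_genome <- function(chrom, size) {
  stopifnot(length(chrom) == length(size), !anyDuplicated(chrom),
            all(size > 0))
  tibble::tibble(chrom = as.character(chrom), size = as.numeric(size))
}

# Internal: assign n elements to chromosomes with probability proportional
# to size (the pooled-genome view of uniform placement).
assign_chroms <- function(genome, n) {
  if (nrow(genome) == 1L) return(rep(1L, n))
  sample.int(nrow(genome), n, replace = TRUE, prob = genome$size)
}

#' Uniformly placed synthetic elements
#'
#' Places `n` elements with the given lengths at positions drawn
#' independently and uniformly over the chromosomes (chromosome chosen
#' with probability proportional to its size, center uniform within the
#' chromosome). Elements may overlap one another; each element lies fully
#' within its chromosome.
#'
#' @param genome A [synth_genome()] tibble.
#' @param n Number of elements (>= 1).
#' @param lengths Integer element lengths, length `n` (recycled if
#'   scalar).
#' @param subfamily Label written to the `subfamily` column.
#' @param seed Optional integer seed (calls `set.seed()`); generators are
#'   deterministic given parameters and seed.
#' @return An element annotation tibble: `chrom`, `start`, `end`
#'   (0-based half-open), `subfamily`, `center`.
#' @export
synth_uniform_annotations <- function(genome, n, lengths,
                                      subfamily = "synthU", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, all(lengths >= 1))
  lengths <- rep_len(as.numeric(lengths), n)
  ci <- assign_chroms(genome, n)
  sz <- genome$size[ci]
  if (any(lengths > sz))
    stop("element length exceeds chromosome size")
  start <- floor(runif(n) * (sz - lengths + 1))
  tibble::tibble(chrom = genome$chrom[ci], start = start,
                 end = start + lengths, subfamily = subfamily) |>
    add_centers() |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Element centers: floor((start + end) / 2), consistent everywhere.
add_centers <- function(el) dplyr::mutate(el, center = floor((.data$start + .data$end) / 2))

#' Clustered synthetic elements (Neyman-Scott process)
#'
#' Emulates the clustered placement of genomic repeats: cluster centers
#' are drawn per chromosome as a Poisson process with `cluster_intensity`
#' expected centers per megabase; each cluster-borne element picks a
#' random center and is displaced by a Gaussian offset with standard
#' deviation `cluster_spread`; the remaining `1 - clustered_fraction` of
#' elements are placed uniformly. All elements are clipped inside their
#' chromosome. If a chromosome draws zero cluster centers while clustered
#' elements were requested, those elements fall back to uniform placement
#' with a warning.
#'
#' @param genome A [synth_genome()] tibble.
#' @param n_elements Total number of elements.
#' @param element_length_mean,element_length_sd Element length
#'   distribution (normal, truncated at 1, rounded).
#' @param cluster_intensity Expected cluster centers per Mb.
#' @param cluster_spread Gaussian offset scale in basepairs.
#' @param clustered_fraction Probability an element is cluster-borne.
#' @param subfamily Label for the `subfamily` column.
#' @inheritParams synth_uniform_annotations
#' @return An element annotation tibble (see
#'   [synth_uniform_annotations()]).
#' @export
synth_clustered_annotations <- function(genome, n_elements,
                                        element_length_mean = 300,
                                        element_length_sd = 50,
                                        cluster_intensity = 2,
                                        cluster_spread = 5000,
                                        clustered_fraction = 0.8,
                                        subfamily = "synthC", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(clustered_fraction >= 0, clustered_fraction <= 1,
            element_length_mean >= 1, n_elements >= 1)
  lengths <- pmax(1, round(rnorm(n_elements, element_length_mean,
                                 element_length_sd)))
  ci <- assign_chroms(genome, n_elements)
  clustered <- runif(n_elements) < clustered_fraction
  center <- numeric(n_elements)
  for (k in seq_len(nrow(genome))) {
    on_k <- which(ci == k)
    if (length(on_k) == 0L) next
    sz <- genome$size[k]
    n_centers <- rpois(1, cluster_intensity * sz / 1e6)
    cl_k <- on_k[clustered[on_k]]
    if (length(cl_k) > 0L && n_centers == 0L) {
      warning("chromosome ", genome$chrom[k],
              " drew no cluster centers; placing its clustered elements uniformly")
      clustered[cl_k] <- FALSE
      cl_k <- integer(0)
    }
    if (n_centers > 0L && length(cl_k) > 0L) {
      ctrs <- runif(n_centers) * sz
      pick <- sample.int(n_centers, length(cl_k), replace = TRUE)
      center[cl_k] <- ctrs[pick] + rnorm(length(cl_k), 0, cluster_spread)
    }
    un_k <- on_k[!clustered[on_k]]
    center[un_k] <- runif(length(un_k)) * sz
  }
  start <- round(center - lengths / 2)
  el <- tibble::tibble(chrom = genome$chrom[ci], start = start,
                       end = start + lengths, subfamily = subfamily)
  sz <- genome$size[ci]
  shift <- pmax(0, -el$start) - pmax(0, el$end - sz)
  el$start <- el$start + shift
  el$end <- el$end + shift
  add_centers(el) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Synthetic open-chromatin peaks
#'
#' Places `n_peaks` fixed-length peaks: with probability `coupling` a peak
#' is centered uniformly inside a randomly chosen element-cluster
#' interval, otherwise uniformly on the genome. With `coupling > 0` but no
#' cluster intervals supplied, all peaks are uniform and a warning is
#' raised.
#'
#' @param genome A [synth_genome()] tibble.
#' @param element_clusters Tibble of cluster intervals (`chrom`, `start`,
#'   `end`) or `NULL`.
#' @param coupling Probability in `[0, 1]` that a peak tracks a cluster.
#' @param n_peaks,peak_length Number and length of peaks.
#' @inheritParams synth_uniform_annotations
#' @return Interval tibble `chrom`, `start`, `end`, clipped inside
#'   chromosomes.
#' @export
synth_open_chromatin <- function(genome, element_clusters, coupling,
                                 n_peaks = 500, peak_length = 400,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coupling >= 0, coupling <= 1, n_peaks >= 1, peak_length >= 1)
  no_clusters <- is.null(element_clusters) || nrow(element_clusters) == 0L
  if (coupling > 0 && no_clusters) {
    warning("no cluster intervals supplied; placing all peaks uniformly")
    coupling <- 0
  }
  in_cluster <- runif(n_peaks) < coupling
  chrom <- character(n_peaks); center <- numeric(n_peaks)
  n_c <- sum(in_cluster)
  if (n_c > 0L) {
    pick <- sample.int(nrow(element_clusters), n_c, replace = TRUE)
    chrom[in_cluster] <- element_clusters$chrom[pick]
    center[in_cluster] <- element_clusters$start[pick] +
      runif(n_c) * (element_clusters$end[pick] - element_clusters$start[pick])
  }
  if (n_c < n_peaks) {
    ci <- assign_chroms(genome, n_peaks - n_c)
    chrom[!in_cluster] <- genome$chrom[ci]
    center[!in_cluster] <- runif(n_peaks - n_c) * genome$size[ci]
  }
  pk <- tibble::tibble(chrom = chrom,
                       start = round(center - peak_length / 2),
                       end = round(center - peak_length / 2) + peak_length)
  sz <- genome$size[match(pk$chrom, genome$chrom)]
  shift <- pmax(0, -pk$start) - pmax(0, pk$end - sz)
  pk$start <- pk$start + shift
  pk$end <- pk$end + shift
  dplyr::arrange(pk, .data$chrom, .data$start)
}

#' Synthetic sequences with controlled dinucleotide content
#'
#' Generates DNA as a first-order Markov chain over A/C/G/T whose
#' transition probabilities are proportional to the requested dinucleotide
#' weights, so the realized dinucleotide frequencies approach the
#' requested profile up to sampling error (exactly, when the weight
#' matrix's row and column marginals agree). A first-order chain suffices
#' because the TRX flexibility score is a dinucleotide statistic.
#'
#' @param lengths Named integer vector: one sequence per entry, names
#'   become sequence names.
#' @param weights Named numeric vector of positive weights over
#'   dinucleotides (subset allowed; missing dinucleotides get weight 0).
#'   Must leave every reachable base with at least one outgoing
#'   transition.
#' @inheritParams synth_uniform_annotations
#' @return A [Biostrings::DNAStringSet].
#' @examples
#' s <- synth_sequences(c(r1 = 500), c(AA = 1, TT = 1, AT = 0.5, TA = 0.5))
#' @export
synth_sequences <- function(lengths, weights, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  dn <- as.vector(outer(bases, bases, paste0))
  if (is.null(names(weights)) || !all(names(weights) %in% dn))
    stop("weights must be named by dinucleotides (AA, AC, ...)")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  w <- setNames(numeric(16), dn)
  w[names(weights)] <- weights
  tm <- matrix(w, 4, 4, byrow = TRUE, dimnames = list(bases, bases))
  row_ok <- rowSums(tm) > 0
  if (!any(row_ok)) stop("degenerate weights: no valid transition")
  start_p <- rowSums(tm); start_p <- start_p / sum(start_p)
  seqs <- vapply(seq_along(lengths), function(i) {
    len <- lengths[i]
    out <- integer(len)
    out[1] <- sample.int(4, 1, prob = start_p)
    for (j in seq_len(len - 1)) {
      p <- tm[out[j], ]
      if (sum(p) <= 0) p <- start_p  # dead-end base: restart from marginal
      out[j + 1] <- sample.int(4, 1, prob = p)
    }
    paste(bases[out], collapse = "")
  }, "")
  names(seqs) <- names(lengths)
  Biostrings::DNAStringSet(seqs)
}

#' Pure lattice insertion history
#'
#' Draws an insertion history from the adjacency choice rule alone, with
#' no spatial dynamics: at each step, with probability `alpha` a site is
#' chosen uniformly among native sites chain-adjacent to a transposed
#' site (falling back to a uniform native draw when none exists, e.g. at
#' the first insertion), otherwise uniformly among all native sites. With
#' `alpha = 1` the transposed sites form a single contiguous block at
#' every step after the first.
#'
#' @param n_total Chain length.
#' @param alpha Adjacency probability in `[0, 1]`.
#' @param n_insertions Number of insertions (<= `n_total`).
#' @inheritParams synth_uniform_annotations
#' @return Tibble with columns `event` and `site`.
#' @export
synth_insertion_history <- function(n_total, alpha, n_insertions = n_total,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(alpha >= 0, alpha <= 1, n_total >= 1)
  if (n_insertions > n_total)
    stop("n_insertions exceeds the chain length")
  kind <- integer(n_total)
  sites <- integer(n_insertions)
  for (t in seq_len(n_insertions)) {
    sites[t] <- choose_insertion_prescribed(kind, alpha)
    kind[sites[t]] <- 1L
  }
  tibble::tibble(event = seq_len(n_insertions), site = sites)
}

#' Write elements or peaks as BED6
#'
#' @param x Interval tibble with `chrom`, `start`, `end` and optionally
#'   `subfamily` (used as the name field).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("subfamily" %in% names(x)) x$subfamily else "."
  bed <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE),
                    name, 0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
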
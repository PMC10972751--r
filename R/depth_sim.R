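#' Simulate paired germline/soma depth tracks with planted regions
#'
#' Emulates the paired sequencing-depth comparison used to detect programmed
#' DNA elimination: both samples fluctuate around their modal depths
#' (negative-binomial noise with a single overdispersion parameter), except
#' inside planted regions. \code{germline_specific} regions have soma depth
#' 0 and germline depth \code{modal_germ * copy_ratio};
#' \code{somatic} regions scale only the soma depth; \code{high_copy_repeat}
#' regions scale both. Default modal depths 32 (germline/testes) and 54
#' (soma/blood) mirror typical paired sequencing runs of this design.
#'
#' @param contigs Named integer vector of contig lengths.
#' @param planted_regions data.frame with columns \code{contig},
#'   \code{start}, \code{end} (0-based half-open), \code{kind} in
#'   \code{c("germline_specific", "somatic", "high_copy_repeat")} and
#'   \code{copy_ratio}. Overlapping regions of different kinds are an error.
#' @param modal_germ,modal_soma Modal depths (> 0).
#' @param noise Overdispersion: depth variance is
#'   \code{mu + noise * mu^2}; \code{noise = 0} gives exact modal depths.
#' @param seed Integer seed.
#' @return List of class \code{"depth_sim"}: \code{germ} and \code{soma}
#'   (each a \code{\link{depth_track}}) and \code{truth} (the planted
#'   regions).
#' @export
simulate_depth_tracks <- function(contigs, planted_regions = NULL,
                                  modal_germ = 32, modal_soma = 54,
                                  noise = 0.02, seed = 1L) {
  stopifnot(modal_germ > 0, modal_soma > 0, noise >= 0)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be a named length vector")
  pr <- planted_regions
  if (!is.null(pr) && nrow(pr)) {
    stopifnot(all(c("contig", "start", "end", "kind", "copy_ratio") %in% names(pr)))
    if (!all(pr$kind %in% c("germline_specific", "somatic", "high_copy_repeat")))
      stop("unknown planted-region kind")
    if (!all(pr$contig %in% names(contigs))) stop("planted region on unknown contig")
    if (any(pr$start < 0) || any(pr$end > contigs[pr$contig]) ||
        any(pr$end <= pr$start))
      stop("planted regions must lie within contig bounds (half-open)")
    for (ct in unique(pr$contig)) {
      rr <- pr[pr$contig == ct, , drop = FALSE]
      rr <- rr[order(rr$start), , drop = FALSE]
      if (nrow(rr) > 1) {
        ov <- rr$start[-1] < rr$end[-nrow(rr)]
        diffkind <- rr$kind[-1] != rr$kind[-nrow(rr)]
        if (any(ov & diffkind))
          stop("overlapping planted regions of different kinds on ", ct)
      }
    }
  }
  draw <- function(n, mu) {
    if (mu <= 0) return(integer(n))
    if (noise == 0) return(rep(as.integer(round(mu)), n))
    size <- 1 / noise
    stats::rnbinom(n, size = size, mu = mu)
  }
  with_seed(stage_seed(seed, "depth"), {
    germ <- list(); soma <- list()
    for (ct in names(contigs)) {
      len <- contigs[[ct]]
      g <- draw(len, modal_germ)
      s <- draw(len, modal_soma)
      if (!is.null(pr) && nrow(pr)) {
        rr <- pr[pr$contig == ct, , drop = FALSE]
        for (r in seq_len(nrow(rr))) {
          idx <- (rr$start[r] + 1L):rr$end[r]
          cr <- rr$copy_ratio[r]
          if (rr$kind[r] == "germline_specific") {
            g[idx] <- draw(length(idx), modal_germ * cr)
            s[idx] <- 0L
          } else if (rr$kind[r] == "somatic") {
            s[idx] <- draw(length(idx), modal_soma * cr)
          } else {
            g[idx] <- draw(length(idx), modal_germ * cr)
            s[idx] <- draw(length(idx), modal_soma * cr)
          }
        }
      }
      germ[[ct]] <- as.integer(g)
      soma[[ct]] <- as.integer(s)
    }
    structure(list(germ = depth_track(germ, "germline"),
                   soma = depth_track(soma, "soma"),
                   truth = pr),
              class = "depth_sim")
  })
}

#' Default planted-region layout for elimination recovery runs
#'
#' Ten 1-Mb contigs with 20 non-overlapping germline-specific regions of
#' 20-60 kb at 10-fold germline copy ratio.
#'
#' @param n_contigs,contig_length,n_regions,copy_ratio Layout parameters.
#' @param seed Integer seed.
#' @return List with \code{contigs} and \code{planted_regions} ready for
#'   \code{\link{simulate_depth_tracks}}.
#' @export
default_depth_layout <- function(n_contigs = 10L, contig_length = 1e6,
                                 n_regions = 20L, copy_ratio = 10,
                                 seed = 1L) {
  contigs <- setNames(rep(as.integer(contig_length), n_contigs),
                      sprintf("ctg%02d", seq_len(n_contigs)))
  with_seed(stage_seed(seed, "depth_layout"), {
    rows <- list()
    per <- ceiling(n_regions / n_contigs)
    k <- 0L
    for (ct in names(contigs)) {
      slots <- seq(0, contig_length - 1e5, length.out = per + 2)[-c(1, per + 2)]
      for (s in slots) {
        if (k >= n_regions) break
        k <- k + 1L
        size <- sample(20000:60000, 1)
        start <- as.integer(s)
        rows[[k]] <- data.frame(contig = ct, start = start,
                                end = start + size,
                                kind = "germline_specific",
                                copy_ratio = copy_ratio,
                                stringsAsFactors = FALSE)
      }
    }
    list(contigs = contigs, planted_regions = do.call(rbind, rows))
  })
}

#' Simulate a k-mer count histogram (k = 31)
#'
#' Unimodal counts centred exactly on \code{modal_copy} (binomial jitter)
#' plus an optional planted heavy tail of abundant k-mers.
#'
#' @param modal_copy Modal k-mer copy number (>= 1).
#' @param abundant_fraction Fraction of k-mers in the heavy tail.
#' @param n_kmers Number of distinct k-mers drawn.
#' @param seed Integer seed.
#' @return data.frame of class \code{"kmer_histogram"} with columns
#'   \code{count} (multiplicity) and \code{n_kmers}.
#' @export
simulate_kmer_histogram <- function(modal_copy, abundant_fraction = 0.01,
                                    n_kmers = 1e5, seed = 1L) {
  stopifnot(modal_copy >= 1, abundant_fraction >= 0, abundant_fraction < 1)
  with_seed(stage_seed(seed, "kmer"), {
    jitter_half <- max(2L, round(modal_copy / 6))
    counts <- modal_copy +
      stats::rbinom(n_kmers, 2L * jitter_half, 0.5) - jitter_half
    counts <- pmax(counts, 1L)
    n_ab <- round(abundant_fraction * n_kmers)
    if (n_ab > 0) {
      hi <- round(modal_copy * stats::runif(n_ab, 5, 50))
      counts[seq_len(n_ab)] <- hi
    }
    tab <- table(counts)
    out <- data.frame(count = as.integer(names(tab)),
                      n_kmers = as.integer(tab))
    class(out) <- c("kmer_histogram", "data.frame")
    out
  })
}
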
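## Germline-vs-soma coverage analysis: modal depths, masking, discontiguous
## fixed-valid-base intervals, log2 enrichment scores, binary segmentation
## and germline-specific region calls, plus the repeat-oriented helpers
## (genomic span, k-mer abundance thresholds, alignment filters, clustered
## somatic repeat windows).

#' Depth track container
#'
#' @param contigs Named list of non-negative integer vectors (per-base depth).
#' @param sample Sample label.
#' @return Object of class \code{"depth_track"}.
#' @export
depth_track <- function(contigs, sample = "sample") {
  stopifnot(is.list(contigs), length(contigs) >= 1,
            !is.null(names(contigs)))
  for (ct in names(contigs)) {
    v <- contigs[[ct]]
    if (any(v < 0) || any(!is.finite(v))) stop("depths must be non-negative")
    contigs[[ct]] <- as.integer(v)
  }
  structure(list(contigs = contigs, sample = sample), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("Depth track '", x$sample, "': ", length(x$contigs), " contigs, ",
      sum(lengths(x$contigs)), " bases\n", sep = "")
  invisible(x)
}

#' Modal sequencing depth
#'
#' The most frequent depth over positions with depth >= 1; ties broken
#' toward the smaller depth.
#'
#' @param track A \code{\link{depth_track}}.
#' @return Integer modal depth.
#' @examples
#' modal_depth(depth_track(list(c1 = c(5L, 5L, 5L, 9L)))) # 5
#' @export
modal_depth <- function(track) {
  stopifnot(inherits(track, "depth_track"))
  v <- unlist(track$contigs, use.names = FALSE)
  v <- v[v >= 1L]
  if (!length(v)) stop("all-zero depth track has no modal depth")
  tab <- tabulate(v)
  which.max(tab)  # first maximum = smallest depth on ties
}

#' Scan parameters for the coverage comparison
#'
#' @param v Valid bases per interval (default 500).
#' @param lo_mode Low-coverage mask rule: \code{"fraction"} (< modal/3 in
#'   both samples) or \code{"absolute"} (< \code{lo_abs} in both samples,
#'   used for the higher-copy run).
#' @param lo_abs Absolute low cutoff when \code{lo_mode = "absolute"}.
#' @param hi_multiple Multiple of modal depth above which positions are
#'   masked when exceeded in both samples (default 3).
#' @param a,b Minimum mean-depth clamps for germline and soma interval means.
#' @param A,B Maximum mean-depth cutoffs.
#' @param call_threshold Log2 enrichment threshold for germline-specific
#'   calls (default 2, i.e. 4-fold normalized enrichment).
#' @return List of class \code{"scan_params"}.
#' @export
scan_params <- function(v = 500L, lo_mode = c("fraction", "absolute"),
                        lo_abs = 10, hi_multiple = 3, a = 10, b = 10,
                        A = 1e8, B = 1e8, call_threshold = 2) {
  lo_mode <- match.arg(lo_mode)
  stopifnot(v >= 1, a > 0, b > 0, a <= A, b <= B, hi_multiple > 0)
  structure(list(v = as.integer(v), lo_mode = lo_mode, lo_abs = lo_abs,
                 hi_multiple = hi_multiple, a = a, b = b, A = A, B = B,
                 call_threshold = call_threshold),
            class = "scan_params")
}

#' Mask low- and high-copy positions
#'
#' A position is masked if depth is low in both samples (below 1/3 of the
#' modal depth, or below an absolute cutoff in the higher-copy variant) or
#' high in both samples (above \code{hi_multiple} times the modal depth).
#' The conjunction ("in both samples") keeps germline-specific regions,
#' where only the soma depth collapses, unmasked.
#'
#' @param germ,soma \code{\link{depth_track}} objects on the same contigs.
#' @param params A \code{\link{scan_params}}.
#' @param modal_g,modal_s Optional precomputed modal depths.
#' @return Named list of logical vectors (\code{TRUE} = masked).
#' @export
mask_positions <- function(germ, soma, params = scan_params(),
                           modal_g = NULL, modal_s = NULL) {
  stopifnot(inherits(germ, "depth_track"), inherits(soma, "depth_track"))
  if (!identical(names(germ$contigs), names(soma$contigs)) ||
      !identical(lengths(germ$contigs), lengths(soma$contigs)))
    stop("germ and soma tracks differ in contigs or lengths")
  if (is.null(modal_g)) modal_g <- modal_depth(germ)
  if (is.null(modal_s)) modal_s <- modal_depth(soma)
  out <- list()
  for (ct in names(germ$contigs)) {
    g <- germ$contigs[[ct]]; s <- soma$contigs[[ct]]
    low <- if (params$lo_mode == "fraction")
      (g < modal_g / 3) & (s < modal_s / 3)
    else
      (g < params$lo_abs) & (s < params$lo_abs)
    high <- (g > params$hi_multiple * modal_g) &
      (s > params$hi_multiple * modal_s)
    out[[ct]] <- low | high
  }
  out
}

#' Group unmasked positions into fixed-valid-base intervals
#'
#' Greedy left-to-right grouping of unmasked positions into intervals each
#' containing exactly \code{v} valid bases. Intervals span masked gaps
#' (hence "discontiguous"); the final interval of a contig may hold fewer
#' than \code{v} valid bases and is flagged partial. Coordinates are
#' 0-based half-open over the genomic span from the first to the last valid
#' base of the interval.
#'
#' @param mask Named list of logical vectors from
#'   \code{\link{mask_positions}}.
#' @param v Valid bases per interval.
#' @return data.frame: contig, start, end, valid, partial.
#' @export
make_intervals <- function(mask, v = 500L) {
  stopifnot(v >= 1)
  rows <- list()
  for (ct in names(mask)) {
    pos <- which(!mask[[ct]])  # 1-based positions of valid bases
    if (!length(pos)) next
    grp <- (seq_along(pos) - 1L) %/% v
    first <- pos[!duplicated(grp)]
    last <- pos[rev(!duplicated(rev(grp)))]
    cnt <- as.vector(table(grp))
    rows[[ct]] <- data.frame(contig = ct, start = first - 1L, end = last,
                             valid = cnt, partial = cnt < v,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score intervals by germline enrichment
#'
#' Per interval, mean depths are computed over valid bases only; the
#' germline mean is clamped to \code{[a, A]} and the soma mean to
#' \code{[b, B]} (the minimum clamps substitute for zero coverage, the
#' maxima exclude ultra-high-copy intervals), and the enrichment score is
#' \deqn{\log_2\frac{\bar g / m_g}{\bar s / m_s}}
#' with \eqn{m_g, m_s} the modal depths. Intervals with both means below
#' their minimum clamps are dropped.
#'
#' @param intervals From \code{\link{make_intervals}}.
#' @param germ,soma Depth tracks.
#' @param params \code{\link{scan_params}}.
#' @param mask The mask used to build the intervals.
#' @param modal_g,modal_s Optional precomputed modal depths.
#' @return The intervals with columns mean_germ, mean_soma, score.
#' @export
interval_enrichment <- function(intervals, germ, soma, params = scan_params(),
                                mask = NULL, modal_g = NULL, modal_s = NULL) {
  if (is.null(modal_g)) modal_g <- modal_depth(germ)
  if (is.null(modal_s)) modal_s <- modal_depth(soma)
  if (is.null(mask)) mask <- mask_positions(germ, soma, params, modal_g, modal_s)
  res <- intervals
  res$mean_germ <- NA_real_
  res$mean_soma <- NA_real_
  for (ct in unique(res$contig)) {
    sel <- which(res$contig == ct)
    g <- germ$contigs[[ct]]; s <- soma$contigs[[ct]]
    ok <- !mask[[ct]]
    ## 0-prepended cumulative sums over valid bases for O(1) interval means
    cg <- c(0, cumsum(ifelse(ok, g, 0)))
    cs <- c(0, cumsum(ifelse(ok, s, 0)))
    cn <- c(0, cumsum(ok))
    st <- res$start[sel]; en <- res$end[sel]
    n <- cn[en + 1L] - cn[st + 1L]
    res$mean_germ[sel] <- (cg[en + 1L] - cg[st + 1L]) / n
    res$mean_soma[sel] <- (cs[en + 1L] - cs[st + 1L]) / n
  }
  drop <- res$mean_germ < params$a & res$mean_soma < params$b
  drop[is.na(drop)] <- TRUE
  res <- res[!drop, , drop = FALSE]
  gme <- pmin(pmax(res$mean_germ, params$a), params$A)
  sme <- pmin(pmax(res$mean_soma, params$b), params$B)
  res$score <- log2((gme / modal_g) / (sme / modal_s))
  rownames(res) <- NULL
  res
}

## max-t statistic over all split points of x; returns list(t, k).
.max_t_split <- function(x, min_width = 2L) {
  n <- length(x)
  ks <- seq(min_width, n - min_width)
  if (!length(ks)) return(list(t = 0, k = NA_integer_))
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  nl <- ks; nr <- n - ks
  sl <- cx[ks]; sr <- cx[n] - sl
  ml <- sl / nl; mr <- sr / nr
  ssl <- cx2[ks] - sl^2 / nl
  ssr <- (cx2[n] - cx2[ks]) - sr^2 / nr
  pooled <- (ssl + ssr) / pmax(n - 2, 1)
  se <- sqrt(pmax(pooled, 1e-12) * (1 / nl + 1 / nr))
  tt <- abs(ml - mr) / se
  k <- ks[which.max(tt)]
  list(t = max(tt), k = k)
}

#' Segment interval scores by recursive binary splitting
#'
#' Circular-binary-segmentation-style changepoint detection on the ordered
#' interval score sequence of each contig: the maximal two-sample t
#' statistic over all split points is compared to its permutation null
#' (no pre-smoothing); splits with permutation p below \code{p_split}
#' recurse into both halves. Deterministic given \code{seed}.
#'
#' @param scored Scored intervals from \code{\link{interval_enrichment}}.
#' @param min_segment Minimum intervals per side of a split (default 2).
#' @param n_perm Permutations per split test (default 1000).
#' @param p_split Permutation p-value required to accept a split
#'   (default 0.01).
#' @param seed Integer seed.
#' @return data.frame: contig, first, last (interval row indices within
#'   contig), start, end (genomic), n_intervals, mean_score.
#' @export
segment_scores <- function(scored, min_segment = 2L, n_perm = 1000L,
                           p_split = 0.01, seed = 1L) {
  rows <- list()
  with_seed(stage_seed(seed, "segment"), {
    for (ct in unique(scored$contig)) {
      sub <- scored[scored$contig == ct, , drop = FALSE]
      x <- sub$score
      segs <- list()
      recurse <- function(lo, hi) {
        n <- hi - lo + 1L
        if (n < 2L * min_segment) {
          segs[[length(segs) + 1L]] <<- c(lo, hi)
          return(invisible(NULL))
        }
        xs <- x[lo:hi]
        obs <- .max_t_split(xs, min_segment)
        if (!is.na(obs$k) && obs$t > 0) {
          exceed <- 0L
          for (p in seq_len(n_perm)) {
            tp <- .max_t_split(sample(xs), min_segment)$t
            if (tp >= obs$t) exceed <- exceed + 1L
          }
          pval <- (exceed + 1) / (n_perm + 1)
          if (pval < p_split) {
            recurse(lo, lo + obs$k - 1L)
            recurse(lo + obs$k, hi)
            return(invisible(NULL))
          }
        }
        segs[[length(segs) + 1L]] <<- c(lo, hi)
        invisible(NULL)
      }
      recurse(1L, nrow(sub))
      for (sg in segs) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ct, first = sg[1], last = sg[2],
          start = sub$start[sg[1]], end = sub$end[sg[2]],
          n_intervals = sg[2] - sg[1] + 1L,
          mean_score = mean(x[sg[1]:sg[2]]),
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call germline-specific regions from score segments
#'
#' Segments whose mean score reaches \code{call_threshold} are merged (when
#' adjacent) into regions; the summary reports the total genomic span and,
#' when a gene map is supplied, the genes fully contained in called regions.
#'
#' @param segments From \code{\link{segment_scores}}.
#' @param call_threshold Log2 score threshold (default 2).
#' @param gene_map Optional data.frame with gene_id, chromosome, start, end.
#' @return List: \code{regions} (contig, start, end, mean_score),
#'   \code{total_bases}, \code{genes} (character vector, possibly empty).
#' @export
call_germline_specific <- function(segments, call_threshold = 2,
                                   gene_map = NULL) {
  hit <- segments[segments$mean_score >= call_threshold, , drop = FALSE]
  regions <- list()
  if (nrow(hit)) {
    hit <- hit[order(hit$contig, hit$start), , drop = FALSE]
    cur <- hit[1, ]
    wsum <- cur$mean_score * cur$n_intervals
    wn <- cur$n_intervals
    for (i in seq_len(nrow(hit))[-1]) {
      if (hit$contig[i] == cur$contig && hit$first[i] == cur$last + 1L) {
        cur$last <- hit$last[i]
        cur$end <- hit$end[i]
        wsum <- wsum + hit$mean_score[i] * hit$n_intervals[i]
        wn <- wn + hit$n_intervals[i]
      } else {
        cur$mean_score <- wsum / wn
        regions[[length(regions) + 1L]] <- cur
        cur <- hit[i, ]
        wsum <- cur$mean_score * cur$n_intervals
        wn <- cur$n_intervals
      }
    }
    cur$mean_score <- wsum / wn
    regions[[length(regions) + 1L]] <- cur
  }
  regions <- if (length(regions))
    do.call(rbind, regions)[, c("contig", "start", "end", "mean_score")]
  else data.frame(contig = character(0), start = integer(0),
                  end = integer(0), mean_score = numeric(0))
  rownames(regions) <- NULL
  genes <- character(0)
  if (!is.null(gene_map) && nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      inr <- gene_map$chromosome == regions$contig[i] &
        gene_map$start >= regions$start[i] & gene_map$end <= regions$end[i]
      genes <- c(genes, gene_map$gene_id[inr])
    }
  }
  list(regions = regions, total_bases = sum(regions$end - regions$start),
       genes = unique(genes))
}

#' Estimated genomic span of a repeat from consensus depth
#'
#' Span = (mean germline depth over bases with depth > \code{min_depth},
#' normalized by the modal germline depth) times the number of such bases.
#'
#' @param profile Integer vector: germline per-base depth along the repeat
#'   consensus.
#' @param modal_g Modal germline depth (e.g. 32).
#' @param min_depth Depth cutoff (default 10).
#' @return Estimated span in bases.
#' @examples
#' repeat_span(rep(320L, 1000), modal_g = 32) # 10000
#' @export
repeat_span <- function(profile, modal_g, min_depth = 10) {
  stopifnot(length(profile) >= 1, modal_g > 0)
  keep <- profile > min_depth
  if (!any(keep)) return(0)
  (mean(profile[keep]) / modal_g) * sum(keep)
}

#' Abundant k-mer threshold
#'
#' Threshold = \code{factor} times the modal k-mer copy number of the
#' histogram; k-mers at or above the threshold are "abundant".
#'
#' @param histogram A \code{kmer_histogram} (or data.frame with columns
#'   count, n_kmers).
#' @param factor Multiple of the modal copy number (default 3).
#' @return List: \code{modal}, \code{threshold}, \code{n_abundant}.
#' @export
kmer_abundance_threshold <- function(histogram, factor = 3) {
  stopifnot(nrow(histogram) >= 1)
  modal <- histogram$count[which.max(histogram$n_kmers)]
  threshold <- factor * modal
  list(modal = modal, threshold = threshold,
       n_abundant = sum(histogram$n_kmers[histogram$count >= threshold]))
}

#' Filter read-to-repeat alignments by coverage fractions
#'
#' Keeps alignments that cover more than 80 percent of the repeat or have
#' more than 80 percent of read bases aligned.
#'
#' @param alignments data.frame with columns \code{repeat_fraction} and
#'   \code{read_fraction} in [0, 1].
#' @param min_fraction Fraction cutoff (default 0.8).
#' @return The retained rows.
#' @export
repeat_alignment_filter <- function(alignments, min_fraction = 0.8) {
  stopifnot(all(c("repeat_fraction", "read_fraction") %in% names(alignments)))
  rf <- alignments$repeat_fraction; qf <- alignments$read_fraction
  if (any(rf < 0 | rf > 1 | qf < 0 | qf > 1))
    stop("coverage fractions must lie in [0, 1]")
  alignments[rf > min_fraction | qf > min_fraction, , drop = FALSE]
}

#' Flag repeat families clustered in 1-Mb windows
#'
#' Tiling windows of \code{window} bases are counted per (family, contig);
#' a family is flagged when some window holds more than \code{min_hits}
#' hits on at least one chromosome, or on every chromosome when
#' \code{centromeric = TRUE} (the pattern expected of centromeric repeats).
#'
#' @param hits data.frame with columns \code{family}, \code{contig},
#'   \code{pos}.
#' @param window Window size in bases (default 1e6).
#' @param min_hits Hit threshold (default 200).
#' @param centromeric Require the pattern on every contig.
#' @param contigs Optional character vector of all contigs (required for
#'   \code{centromeric = TRUE}).
#' @return Character vector of flagged families.
#' @export
somatic_repeat_windows <- function(hits, window = 1e6, min_hits = 200,
                                   centromeric = FALSE, contigs = NULL) {
  stopifnot(all(c("family", "contig", "pos") %in% names(hits)))
  if (centromeric && is.null(contigs)) contigs <- unique(hits$contig)
  flagged <- character(0)
  for (fam in unique(hits$family)) {
    h <- hits[hits$family == fam, , drop = FALSE]
    per_contig <- vapply(split(h$pos, h$contig), function(p) {
      max(table(floor(p / window)))
    }, numeric(1))
    ok <- per_contig > min_hits
    pass <- if (centromeric)
      length(ok) == length(contigs) && all(ok)
    else any(ok)
    if (pass) flagged <- c(flagged, fam)
  }
  flagged
}
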
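#' Builder configuration
#'
#' Bundles the thresholds used when constructing a haplotype map from a
#' phased panel. Defaults are the published genome-wide-map parameters:
#' candidate SNPs need a global MAF of at least 10% and must not differ in
#' MAF by more than 10% between sub-populations; anchors are LD-pruned so no
#' pair within a 10 kb window (sliding 5 SNPs at a time) has r-squared above
#' 0.10; members join a block when their r-squared with the anchor is at
#' least 0.85 and they lie within 10,000 kb of it; anchors claim members in
#' decreasing order of LD score computed over a 1 cM window.
#'
#' @param min_maf Global MAF floor (default 0.10).
#' @param max_pop_maf_diff Maximum spread (max minus min) of per-population
#'   MAF (default 0.10).
#' @param anchor_r2_max Pruning threshold (default 0.10).
#' @param prune_window_bp Pruning window (default 10,000 bp).
#' @param prune_slide_snps Window slide in SNPs (default 5).
#' @param member_r2_min Member admission threshold (default 0.85).
#' @param block_window_bp Maximum anchor-member distance (default 1e7 bp).
#' @param ldscore_window_cm LD-score window on either side (default 1 cM).
#' @return A list of class `builder_config`.
#' @export
builder_config <- function(min_maf = 0.10, max_pop_maf_diff = 0.10,
                           anchor_r2_max = 0.10, prune_window_bp = 10000,
                           prune_slide_snps = 5L, member_r2_min = 0.85,
                           block_window_bp = 1e7, ldscore_window_cm = 1.0) {
  stopifnot(min_maf > 0, min_maf < 1, max_pop_maf_diff > 0, max_pop_maf_diff < 1,
            anchor_r2_max > 0, anchor_r2_max < 1, member_r2_min > 0,
            member_r2_min < 1, prune_window_bp > 0, prune_slide_snps >= 1,
            block_window_bp > 0, ldscore_window_cm > 0)
  structure(list(min_maf = min_maf, max_pop_maf_diff = max_pop_maf_diff,
                 anchor_r2_max = anchor_r2_max, prune_window_bp = prune_window_bp,
                 prune_slide_snps = as.integer(prune_slide_snps),
                 member_r2_min = member_r2_min, block_window_bp = block_window_bp,
                 ldscore_window_cm = ldscore_window_cm),
            class = "builder_config")
}

#' Construct a phased panel
#'
#' @param snps Data.frame with columns `chrom`, `pos`, `name`, `major`,
#'   `minor`; a `maf` column is recomputed from the haplotypes.
#' @param haplotypes Integer/numeric matrix of allele indicators (0 = major,
#'   1 = minor); one row per haplotype (two per individual), one column per
#'   SNP, in the order of `snps`.
#' @param populations Optional population label per individual (length
#'   `nrow(haplotypes) / 2`).
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(snps, haplotypes, populations = NULL) {
  snps <- as.data.frame(snps)
  stopifnot(all(c("chrom", "pos", "name", "major", "minor") %in% names(snps)),
            is.matrix(haplotypes), ncol(haplotypes) == nrow(snps),
            nrow(haplotypes) %% 2L == 0L)
  if (!all(haplotypes %in% c(0, 1))) stop("haplotype entries must be 0 or 1")
  if (anyDuplicated(snps$name)) stop("duplicate SNP names in panel")
  if (!is.null(populations) &&
      length(populations) != nrow(haplotypes) / 2L) {
    stop("populations must have one label per individual")
  }
  storage.mode(haplotypes) <- "double"
  colnames(haplotypes) <- snps$name
  # keep the 0 = major, 1 = minor coding honest: relabel columns whose
  # "minor" indicator is the more frequent allele
  maf <- colMeans(haplotypes)
  flip <- maf > 0.5
  if (any(flip)) {
    haplotypes[, flip] <- 1 - haplotypes[, flip]
    tmp <- snps$major[flip]
    snps$major[flip] <- snps$minor[flip]
    snps$minor[flip] <- tmp
  }
  snps$maf <- colMeans(haplotypes)
  structure(list(snps = snps, haplotypes = haplotypes,
                 populations = populations),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("phased_panel: %d SNPs x %d haplotypes (%d individuals)%s\n",
              nrow(x$snps), nrow(x$haplotypes), nrow(x$haplotypes) / 2L,
              if (is.null(x$populations)) "" else
                sprintf(", %d populations", length(unique(x$populations)))))
  invisible(x)
}

#' Squared allelic correlation between two panel SNPs
#'
#' On phased haplotypes the squared Pearson correlation of the two 0/1
#' allele-indicator columns equals the classical D^2 / (pA pa pB pb).
#' r-squared is symmetric and blind to global 0/1 relabeling of a column.
#'
#' @param panel A `phased_panel`.
#' @param snp_i,snp_j SNP names.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(panel, snp_i, snp_j) {
  i <- match(snp_i, panel$snps$name)
  j <- match(snp_j, panel$snps$name)
  if (is.na(i) || is.na(j)) stop("SNP not in panel: ",
                                 if (is.na(i)) snp_i else snp_j)
  x <- panel$haplotypes[, i]
  y <- panel$haplotypes[, j]
  if (var(x) == 0 || var(y) == 0) {
    stop("undefined correlation: monomorphic SNP")
  }
  unname(cor(x, y)^2)
}

# Full r2 matrix over a set of columns; NA (monomorphic) -> 0.
r2_matrix <- function(H, cols) {
  r <- suppressWarnings(cor(H[, cols, drop = FALSE]))
  r[is.na(r)] <- 0
  r * r
}

#' Filter candidate SNPs by global and per-population MAF
#'
#' Keeps SNPs whose global MAF is at least `cfg$min_maf` and whose
#' per-population MAF spread (max minus min) is at most
#' `cfg$max_pop_maf_diff`. When the panel carries no population labels the
#' population filter is skipped with a warning so that single-population
#' synthetic panels remain usable.
#'
#' @param panel A `phased_panel`.
#' @param cfg A `builder_config`.
#' @return The filtered `phased_panel`.
#' @export
filter_candidates <- function(panel, cfg = builder_config()) {
  maf <- panel$snps$maf
  keep <- maf >= cfg$min_maf & maf <= 0.5
  if (is.null(panel$populations)) {
    warning("panel has no population labels; skipping per-population MAF filter")
  } else {
    hap_pop <- rep(panel$populations, each = 2L)
    pops <- unique(hap_pop)
    freqs <- vapply(pops, function(p) {
      colMeans(panel$haplotypes[hap_pop == p, , drop = FALSE])
    }, numeric(nrow(panel$snps)))
    pmaf <- pmin(freqs, 1 - freqs)  # minor-allele frequency within population
    spread <- apply(pmaf, 1, max) - apply(pmaf, 1, min)
    keep <- keep & spread <= cfg$max_pop_maf_diff
  }
  subset_panel(panel, which(keep))
}

subset_panel <- function(panel, idx) {
  phased_panel(panel$snps[idx, , drop = FALSE],
               panel$haplotypes[, idx, drop = FALSE],
               panel$populations)
}

#' LD-prune SNPs into an independent anchor set
#'
#' Windowed pruning in the style of PLINK's pairwise pruning: within every
#' window of `cfg$prune_window_bp` (window starts step forward
#' `cfg$prune_slide_snps` SNPs at a time), pairs with r-squared above
#' `cfg$anchor_r2_max` are broken by dropping one SNP. The lower-MAF SNP of
#' an offending pair is dropped; on ties, the later position. Passes repeat
#' until no window contains an offending pair, and a final single-SNP-step
#' sweep guarantees the post-condition for every pair within the bp window
#' regardless of SNP density (a bp-defined window with a SNP-count slide can
#' otherwise skip close pairs when SNPs are sparse).
#'
#' @param panel A `phased_panel` (typically already MAF-filtered).
#' @param cfg A `builder_config`.
#' @return Character vector of surviving SNP names, original order preserved.
#' @export
prune_anchors <- function(panel, cfg = builder_config()) {
  snps <- panel$snps
  H <- panel$haplotypes
  alive <- rep(TRUE, nrow(snps))
  ord <- order(snps$chrom, snps$pos, method = "radix")
  slide <- cfg$prune_slide_snps
  repeat {
    dropped_any <- FALSE
    for (chrom in unique(snps$chrom[ord])) {
      cidx <- ord[snps$chrom[ord] == chrom]
      starts <- seq(1L, length(cidx), by = slide)
      for (s in starts) {
        w0 <- cidx[[s]]
        inwin <- cidx[seq(s, length(cidx))]
        inwin <- inwin[snps$pos[inwin] - snps$pos[[w0]] <= cfg$prune_window_bp]
        inwin <- inwin[alive[inwin]]
        if (length(inwin) < 2L) next
        r2 <- r2_matrix(H, inwin)
        repeat {
          r2[lower.tri(r2, diag = TRUE)] <- 0
          worst <- which(r2 > cfg$anchor_r2_max, arr.ind = TRUE)
          if (!nrow(worst)) break
          i <- inwin[[worst[1, 1]]]
          j <- inwin[[worst[1, 2]]]
          drop <- if (snps$maf[[i]] < snps$maf[[j]]) i
                  else if (snps$maf[[j]] < snps$maf[[i]]) j
                  else if (snps$pos[[i]] > snps$pos[[j]]) i else j
          alive[[drop]] <- FALSE
          dropped_any <- TRUE
          k <- match(drop, inwin)
          inwin <- inwin[-k]
          r2 <- r2[-k, -k, drop = FALSE]
          if (length(inwin) < 2L) break
        }
      }
    }
    if (!dropped_any && slide == 1L) break
    if (!dropped_any) slide <- 1L  # verification sweep over every start
  }
  snps$name[alive]
}

#' Genetic map (physical position to centimorgans)
#'
#' @param knots Data.frame with columns `chrom`, `pos` (bp) and `cm`
#'   (cumulative genetic position), nondecreasing in `pos` per chromosome.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(knots) {
  knots <- as.data.frame(knots)
  stopifnot(all(c("chrom", "pos", "cm") %in% names(knots)))
  knots <- knots[order(knots$chrom, knots$pos, method = "radix"), ]
  for (chrom in unique(knots$chrom)) {
    cm <- knots$cm[knots$chrom == chrom]
    if (is.unsorted(cm)) stop("genetic map cM must be nondecreasing: ", chrom)
  }
  structure(knots, class = c("genetic_map", "data.frame"))
}

#' Read a whitespace-delimited `chrom pos cM` genetic map file
#' @param path File path.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  d <- read.table(path, header = FALSE, col.names = c("chrom", "pos", "cm"),
                  colClasses = c("character", "integer", "numeric"))
  genetic_map(d)
}

# Linear interpolation between knots; outside the knots, the nearest knot's
# cM is used. With no genetic map, 1 cM is approximated as 1 Mb.
interpolate_cm <- function(gmap, chrom, pos) {
  if (is.null(gmap)) return(pos / 1e6)
  out <- numeric(length(pos))
  for (c_ in unique(chrom)) {
    k <- gmap[gmap$chrom == c_, ]
    sel <- chrom == c_
    if (nrow(k) == 0L) stop("chromosome absent from genetic map: ", c_)
    if (nrow(k) == 1L) {
      out[sel] <- k$cm
    } else {
      out[sel] <- approx(k$pos, k$cm, xout = pos[sel], rule = 2)$y
    }
  }
  out
}

#' LD score of a SNP
#'
#' Sum of r-squared between the SNP and every other panel SNP within
#' `window_cm` on either side (genetic distance via `gmap`, or 1 Mb = 1 cM
#' when no map is given), plus the self term 1.0.
#'
#' @param panel A `phased_panel`.
#' @param snp SNP name.
#' @param gmap Optional `genetic_map`.
#' @param window_cm Window half-width in cM (default 1).
#' @return Nonnegative score (at least 1, the self term).
#' @export
ld_score <- function(panel, snp, gmap = NULL, window_cm = 1.0) {
  ld_scores(panel, snp, gmap, window_cm)[[1]]
}

# Vectorized LD scores for a set of SNPs (all panel SNPs are potential
# neighbors). Uses a precomputed full r2 matrix when supplied.
ld_scores <- function(panel, snps, gmap = NULL, window_cm = 1.0, r2 = NULL) {
  all_cm <- interpolate_cm(gmap, panel$snps$chrom, panel$snps$pos)
  idx <- match(snps, panel$snps$name)
  if (anyNA(idx)) stop("SNP not in panel: ", snps[which(is.na(idx))[1]])
  H <- panel$haplotypes
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    nb <- which(panel$snps$chrom == panel$snps$chrom[[i]] &
                  abs(all_cm - all_cm[[i]]) <= window_cm)
    nb <- nb[nb != i]
    if (!length(nb)) {
      out[[k]] <- 1.0
    } else if (!is.null(r2)) {
      out[[k]] <- 1.0 + sum(r2[i, nb])
    } else {
      x <- H[, i]
      r <- suppressWarnings(cor(x, H[, nb, drop = FALSE]))
      r[is.na(r)] <- 0
      out[[k]] <- 1.0 + sum(r * r)
    }
  }
  out
}

#' Greedily build LD blocks around anchor SNPs
#'
#' Anchors are processed in decreasing order of LD score (ties broken by
#' (chrom, pos)); each processed anchor claims every still-unassigned
#' non-anchor SNP on its chromosome within `cfg$block_window_bp` whose
#' r-squared with the anchor is at least `cfg$member_r2_min`. A SNP eligible
#' for several blocks therefore joins the highest-LD-score anchor. Member
#' phase is the sign of the covariance between member and anchor indicator
#' columns; the block's prior frequency is the anchor's MAF.
#'
#' @param panel A `phased_panel` (the filtered candidate set).
#' @param anchors Character vector of anchor SNP names (from
#'   [prune_anchors()]).
#' @param gmap Optional `genetic_map` for the LD-score ordering.
#' @param cfg A `builder_config`.
#' @return A `haplotype_map`.
#' @export
build_blocks <- function(panel, anchors, gmap = NULL, cfg = builder_config()) {
  snps <- panel$snps
  H <- panel$haplotypes
  aidx <- match(anchors, snps$name)
  if (anyNA(aidx)) stop("anchor not in panel: ", anchors[which(is.na(aidx))[1]])

  use_full_r2 <- nrow(snps) <= 4000L
  r2full <- if (use_full_r2) r2_matrix(H, seq_len(nrow(snps))) else NULL
  sc <- ld_scores(panel, anchors, gmap, cfg$ldscore_window_cm, r2 = r2full)
  ord <- order(-sc, snps$chrom[aidx], snps$pos[aidx], method = "radix")

  assigned <- rep(NA_character_, nrow(snps))
  assigned[aidx] <- snps$name[aidx]           # anchors are their own blocks
  phase <- rep("+", nrow(snps))

  for (k in ord) {
    a <- aidx[[k]]
    cand <- which(is.na(assigned) &
                    snps$chrom == snps$chrom[[a]] &
                    abs(snps$pos - snps$pos[[a]]) <= cfg$block_window_bp)
    if (!length(cand)) next
    if (use_full_r2) {
      r2v <- r2full[a, cand]
      rsign <- suppressWarnings(cor(H[, a], H[, cand, drop = FALSE]))
      rsign[is.na(rsign)] <- 0
    } else {
      rsign <- suppressWarnings(cor(H[, a], H[, cand, drop = FALSE]))
      rsign[is.na(rsign)] <- 0
      r2v <- rsign * rsign
    }
    take <- which(r2v >= cfg$member_r2_min)
    if (!length(take)) next
    assigned[cand[take]] <- snps$name[[a]]
    phase[cand[take]] <- ifelse(rsign[take] >= 0, "+", "-")
  }

  keep <- which(!is.na(assigned))
  haplotype_map(data.frame(
    chrom = snps$chrom[keep], pos = snps$pos[keep], name = snps$name[keep],
    major = snps$major[keep], minor = snps$minor[keep],
    maf = round(snps$maf[keep], 6), anchor = assigned[keep],
    phase = phase[keep], stringsAsFactors = FALSE))
}

#' One-step map construction from a phased panel
#'
#' Runs [filter_candidates()], [prune_anchors()] and [build_blocks()] with a
#' single configuration. Deterministic: the same panel and configuration
#' always produce a byte-identical map file.
#'
#' @inheritParams build_blocks
#' @param cfg A `builder_config`.
#' @return A `haplotype_map`.
#' @export
build_map <- function(panel, gmap = NULL, cfg = builder_config()) {
  cand <- suppressWarnings(filter_candidates(panel, cfg))
  anchors <- prune_anchors(cand, cfg)
  build_blocks(cand, anchors, gmap, cfg)
}

#' Expected per-block LOD contribution of a locus (information score)
#'
#' Under Hardy-Weinberg genotype priors p(AA) = (1-f)^2, p(AB) = 2f(1-f),
#' p(BB) = f^2 at allele frequency f, the expected LOD contribution of a
#' fully informative locus is the entropy-like quantity
#' -sum_theta p(theta) log10 p(theta). It is maximal at f = 0.5, where it
#' equals 1.5 log10(2), approximately 0.4515; this is why map construction
#' prefers common variants.
#'
#' @param maf Minor-allele frequency, in (0, 0.5]. Vectorized.
#' @return Nonnegative score.
#' @export
expected_block_information <- function(maf) {
  if (any(is.na(maf) | maf <= 0 | maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  p <- cbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  -rowSums(p * log10(p))
}
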
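# Shared fixtures and independent oracles. Oracles deliberately use the
# most direct formulation available (linear-space products, closed-form D^2
# ratio, exhaustive enumeration) so they cannot share bugs with the
# log-space / vectorized implementation paths they check.

# two blocks, five SNPs, including a negative-phase member
toy_map <- function() {
  haplotype_map(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 250L, 400L, 100L, 300L),
    name = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    major = c("A", "C", "G", "T", "A"),
    minor = c("G", "T", "A", "C", "C"),
    maf = c(0.3, 0.28, 0.31, 0.5, 0.49),
    anchor = c("rs1", "rs1", "rs1", "rs4", "rs4"),
    phase = c("+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE))
}

make_read <- function(qname, chrom, pos, seq, bq = 30L, mapq = 60L,
                      flag = 0L, cigar = NULL) {
  data.frame(qname = qname, flag = as.integer(flag), chrom = chrom,
             pos = as.integer(pos), mapq = as.integer(mapq),
             cigar = if (is.null(cigar)) sprintf("%dM", nchar(seq)) else cigar,
             seq = seq, qual = strrep(intToUtf8(bq + 33L), nchar(seq)),
             stringsAsFactors = FALSE)
}

# fingerprint with hand-chosen log10 likelihoods, bound to a map
manual_fingerprint <- function(map, ll_by_anchor, n_obs_by_anchor = NULL,
                               sample_id = "manual") {
  fp <- build_fingerprint(NULL, map, sample_id = sample_id)
  for (a in names(ll_by_anchor)) {
    i <- match(a, fp$blocks$anchor)
    stopifnot(!is.na(i))
    fp$blocks[i, c("ll_AA", "ll_AB", "ll_BB")] <- ll_by_anchor[[a]]
    fp$blocks$n_obs[i] <- if (is.null(n_obs_by_anchor)) 1L else
      n_obs_by_anchor[[a]]
  }
  fp
}

# linear-space brute-force per-block LOD term (independent oracle)
brute_block_lod <- function(lx, ly, prior, cap = -3) {
  num <- sum(10^lx * 10^ly * prior)
  den <- sum(10^lx * prior) * sum(10^ly * prior)
  max(log10(num / den), cap)
}

# closed-form r2 on phased 0/1 vectors: D^2 / (pA pa pB pb)
r2_closed_form <- function(x, y) {
  p1 <- mean(x); q1 <- mean(y)
  D <- mean(x == 1 & y == 1) - p1 * q1
  D^2 / (p1 * (1 - p1) * q1 * (1 - q1))
}

# panel straight from an explicit haplotype table
panel_from_table <- function(H, chrom = "chr1", pos = NULL,
                             populations = NULL) {
  n <- ncol(H)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n)
  phased_panel(data.frame(chrom = chrom, pos = pos,
                          name = sprintf("s%02d", seq_len(n)),
                          major = "A", minor = "G",
                          stringsAsFactors = FALSE),
               H, populations)
}

# random fingerprint pair on a map (seeded by the caller)
random_fingerprint <- function(map, id = "rand", p_empty = 0.1) {
  anchors <- map_anchors(map)$name
  ll <- lapply(anchors, function(a) {
    if (runif(1) < p_empty) c(0, 0, 0) else -sort(runif(3, 0, 8))
  })
  names(ll) <- anchors
  nob <- lapply(ll, function(l) if (all(l == 0)) 0L else sample(1:10, 1))
  manual_fingerprint(map, ll, nob, sample_id = id)
}

pair_lods_for_test <- function(fps, map) {
  ids <- names(fps)
  out <- c()
  for (i in 1:2) for (j in (i + 1):3) {
    out <- c(out, total_lod(fps[[ids[i]]], fps[[ids[j]]], map)$lod)
  }
  out
}

# small simulated world shared by several test files
small_world <- function(n_blocks = 120, n_haplotypes = 300, seed = 101) {
  panel <- simulate_panel(population_model(
    n_blocks = n_blocks, n_haplotypes = n_haplotypes, seed = seed))
  list(panel = panel, map = map_from_panel(panel))
}
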
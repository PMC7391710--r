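test_that("pairwise_r2 matches the closed-form D^2 ratio and its symmetries", {
  # 8-haplotype joint table n(00)=3, n(01)=1, n(10)=1, n(11)=3:
  # D = 3/8 - 1/2 * 1/2 = 1/8, r2 = (1/64)/(1/16) = 0.25
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  panel <- panel_from_table(cbind(x, y, 1 - x, x))
  expect_equal(pairwise_r2(panel, "s01", "s02"), 0.25)
  expect_equal(pairwise_r2(panel, "s01", "s02"),
               r2_closed_form(x, y))

  expect_equal(pairwise_r2(panel, "s01", "s04"), 1.0)  # identical columns
  expect_equal(pairwise_r2(panel, "s01", "s03"), 1.0)  # complement: sign-blind
  # symmetry
  expect_equal(pairwise_r2(panel, "s02", "s01"), pairwise_r2(panel, "s01", "s02"))

  mono <- panel_from_table(cbind(x, rep(0, 8)))
  expect_error(pairwise_r2(mono, "s01", "s02"), "monomorphic")
  expect_error(pairwise_r2(panel, "s01", "nope"), "not in panel")
})

test_that("pairwise_r2 is flip-invariant on random tables", {
  set.seed(20)
  for (rep in 1:20) {
    H <- matrix(rbinom(60 * 2, 1, runif(1, 0.2, 0.5)), ncol = 2)
    if (var(H[, 1]) == 0 || var(H[, 2]) == 0) next
    p <- panel_from_table(H)
    pf <- panel_from_table(cbind(1 - H[, 1], H[, 2]))
    expect_equal(pairwise_r2(p, "s01", "s02"), pairwise_r2(pf, "s01", "s02"),
                 tolerance = 1e-12)
    expect_equal(pairwise_r2(p, "s01", "s02"), r2_closed_form(H[, 1], H[, 2]),
                 tolerance = 1e-12)
  }
})

test_that("filter_candidates applies global and per-population MAF rules", {
  set.seed(7)
  n_ind <- 200
  pops <- rep(c("P1", "P2"), each = n_ind / 2)
  gen <- function(f1, f2) c(rbinom(n_ind, 1, f1), rbinom(n_ind, 1, f2))
  H <- cbind(gen(0.05, 0.05),   # rare: out
             gen(0.10, 0.25),   # pop diff 0.15: out
             gen(0.30, 0.35))   # kept
  panel <- phased_panel(
    data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
               name = c("rare", "diff", "good"), major = "A", minor = "G",
               stringsAsFactors = FALSE),
    H, populations = pops)
  kept <- filter_candidates(panel, builder_config())
  expect_equal(kept$snps$name, "good")

  nolabel <- phased_panel(panel$snps, H)
  expect_warning(kept2 <- filter_candidates(nolabel), "population")
  expect_false("rare" %in% kept2$snps$name)
  expect_true("diff" %in% kept2$snps$name)  # diff filter skipped
})

test_that("prune_anchors enforces pairwise independence within windows", {
  set.seed(31)
  n <- 100
  a <- rbinom(n, 1, 0.4)
  b <- rbinom(n, 1, 0.4)
  # two perfectly correlated SNPs 100 bp apart -> one survives
  p <- panel_from_table(cbind(a, a), pos = c(100L, 200L))
  expect_length(prune_anchors(p), 1L)
  # two independent SNPs -> both survive
  p2 <- panel_from_table(cbind(a, b), pos = c(100L, 200L))
  expect_length(prune_anchors(p2), 2L)

  # 10-SNP chromosome with one correlated triple; exhaustive post-check
  cols <- replicate(10, rbinom(n, 1, runif(1, 0.25, 0.5)))
  cols[, 5] <- cols[, 4]
  flip <- rbinom(n, 1, 0.02); cols[, 6] <- ifelse(flip == 1, 1 - cols[, 4], cols[, 4])
  pos <- seq(100L, by = 500L, length.out = 10L)
  p3 <- panel_from_table(cols, pos = pos)
  surv <- prune_anchors(p3, builder_config())
  idx <- match(surv, p3$snps$name)
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (i >= j) next
      if (abs(pos[idx[i]] - pos[idx[j]]) > 10000) next
      expect_lte(pairwise_r2(p3, surv[i], surv[j]), 0.10)
    }
  }
})

test_that("prune tie-breaking drops the lower-MAF SNP deterministically", {
  set.seed(8)
  a <- rbinom(300, 1, 0.45)
  # identical columns have equal MAF: tie -> later position dropped
  p_tie <- panel_from_table(cbind(a, a), pos = c(100L, 200L))
  expect_equal(prune_anchors(p_tie), "s01")
  # unequal maf: drop lower
  b <- a; b[sample(which(a == 1), 20)] <- 0  # lower maf, still r2 > 0.1
  p_diff <- panel_from_table(cbind(a, b), pos = c(100L, 200L))
  expect_equal(prune_anchors(p_diff), "s01")
  p_diff_rev <- panel_from_table(cbind(b, a), pos = c(100L, 200L))
  expect_equal(prune_anchors(p_diff_rev), "s02")
})

test_that("ld_score sums windowed r2 with the self term", {
  set.seed(12)
  a <- rbinom(200, 1, 0.4)
  b <- rbinom(200, 1, 0.4)
  # isolated SNP (neighbor outside 1 cM = 1 Mb under the default proxy)
  p <- panel_from_table(cbind(a, b), pos = c(100L, 2000000L))
  expect_equal(ld_score(p, "s01"), 1.0)
  # perfect-LD neighbor inside the window
  p2 <- panel_from_table(cbind(a, a, b), pos = c(100L, 200L, 5000L))
  expect_equal(ld_score(p2, "s01"),
               2.0 + pairwise_r2(p2, "s01", "s03"))
  # genetic map stretches the 5 kb gap beyond 1 cM -> neighbor excluded
  gmap <- genetic_map(data.frame(chrom = "chr1", pos = c(0L, 1000L, 10000L),
                                 cm = c(0, 0.1, 25)))
  expect_equal(ld_score(p2, "s01", gmap = gmap),
               2.0)  # s02 still within, s03 now 13+ cM away
})

test_that("build_blocks assigns members greedily by LD score with phase", {
  set.seed(23)
  n <- 600
  a <- rbinom(n, 1, 0.4)
  a2 <- rbinom(n, 1, 0.45)
  # anchor s01 with two perfect members, plus an independent anchor s04
  p <- panel_from_table(cbind(a, a, a, a2), pos = c(100L, 300L, 500L, 700L))
  m <- build_blocks(p, anchors = c("s01", "s04"))
  expect_equal(sum(m$anchor == "s01"), 3L)
  expect_equal(sum(m$anchor == "s04"), 1L)

  # member 15 Mb from its only correlated anchor stays out of the block
  pfar <- panel_from_table(cbind(a, a), pos = c(100L, 15000100L))
  mfar <- build_blocks(pfar, anchors = "s01")
  expect_equal(nrow(mfar), 1L)

  # candidates eligible for two anchors join the higher-LD-score one: s01
  # is a clean copy of the haplotype column while s05 carries extra noise,
  # so every pairwise r2 (and hence the LD score) favors s01
  noise <- function(v, s) ifelse(runif(n) < s, 1 - v, v)
  b <- rbinom(n, 1, 0.4)
  p2 <- panel_from_table(cbind(a, noise(a, 0.01), a, b, noise(a, 0.02)),
                         pos = c(100L, 200L, 300L, 400L, 500L))
  sc <- vapply(c("s01", "s05"), function(s) ld_score(p2, s), numeric(1))
  expect_gt(sc[["s01"]], sc[["s05"]])
  m2 <- build_blocks(p2, anchors = c("s01", "s05"))
  shared <- m2[m2$name %in% c("s02", "s03"), ]
  expect_true(all(shared$anchor == "s01"))
})

test_that("build_blocks phases negative-correlation members as '-'", {
  set.seed(42)
  a <- rbinom(1000, 1, 0.5)
  # complementary coding with minor frequency kept strictly below 0.5:
  # a genuine negative-phase member
  m_col <- 1 - a
  m_col[sample(which(m_col == 1), 40)] <- 0
  stopifnot(mean(m_col) < 0.5)
  p <- panel_from_table(cbind(a, m_col), pos = c(100L, 200L))
  m <- build_blocks(p, anchors = "s01")
  expect_equal(m$phase[m$name == "s02"], "-")
  expect_equal(nrow(validate_map(m, p, min_maf = 0.05)), 0L)
})

test_that("expected_block_information matches the closed form", {
  expect_equal(expected_block_information(0.5), 1.5 * log10(2), tolerance = 1e-12)
  expect_equal(expected_block_information(0.1), 0.22817804, tolerance = 1e-6)
  expect_lt(expected_block_information(1e-9), 1e-6)  # degenerate prior limit
  expect_error(expected_block_information(0), "0, 0.5")
  expect_error(expected_block_information(0.6), "0, 0.5")
  # vectorized & monotone increasing on (0, 0.5]
  grid <- seq(0.01, 0.5, by = 0.01)
  vals <- expected_block_information(grid)
  expect_false(is.unsorted(vals))
})

test_that("builder output satisfies its own constraints (exhaustive check)", {
  w <- small_world(n_blocks = 40, n_haplotypes = 800, seed = 77)
  built <- build_map(w$panel)
  cfg <- builder_config()
  blocks <- map_blocks(built)
  for (b in blocks) {
    for (k in seq_len(nrow(b))[-1]) {
      expect_gte(pairwise_r2(w$panel, b$name[k], b$name[1]), cfg$member_r2_min)
      expect_lte(abs(b$pos[k] - b$pos[1]), cfg$block_window_bp)
    }
  }
  anchors <- map_anchors(built)
  for (i in seq_len(nrow(anchors) - 1)) {
    j <- i + 1
    while (j <= nrow(anchors) &&
           anchors$chrom[j] == anchors$chrom[i] &&
           anchors$pos[j] - anchors$pos[i] <= cfg$prune_window_bp) {
      expect_lte(pairwise_r2(w$panel, anchors$name[i], anchors$name[j]),
                 cfg$anchor_r2_max)
      j <- j + 1
    }
  }
})

test_that("map construction is deterministic: byte-identical repeat builds", {
  w <- small_world(n_blocks = 25, n_haplotypes = 200, seed = 13)
  f1 <- withr::local_tempfile(fileext = ".map")
  f2 <- withr::local_tempfile(fileext = ".map")
  write_map(build_map(w$panel), f1)
  write_map(build_map(w$panel), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
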
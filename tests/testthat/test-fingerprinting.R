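test_that("observation_likelihood implements the error-switch model", {
  expect_equal(observation_likelihood("MAJOR", 0.01, "AA"), 0.99)
  expect_equal(observation_likelihood("MAJOR", 0.01, "BB"), 0.01)
  expect_equal(observation_likelihood("MINOR", 0.01, "AA"), 0.01)
  expect_equal(observation_likelihood("MINOR", 0.01, "BB"), 0.99)
  # AB is 0.5 regardless of the error probability
  for (e in c(1e-6, 0.01, 0.3, 0.5)) {
    expect_equal(observation_likelihood("MAJOR", e, "AB"), 0.5)
    expect_equal(observation_likelihood("MINOR", e, "AB"), 0.5)
  }
  # normalization: MAJOR + MINOR likelihoods sum to 1 for every genotype
  set.seed(3)
  for (g in c("AA", "AB", "BB")) {
    e <- runif(20, 1e-6, 0.5)
    expect_equal(observation_likelihood(rep("MAJOR", 20), e, rep(g, 20)) +
                   observation_likelihood(rep("MINOR", 20), e, rep(g, 20)),
                 rep(1, 20))
  }
  expect_error(observation_likelihood("MAJOR", 0, "AA"))
  expect_error(observation_likelihood("MAJOR", 0.6, "AA"))
})

test_that("block_likelihoods is the log of the linear-space product", {
  empty <- block_likelihoods(data.frame(allele = character(),
                                        error_prob = numeric(),
                                        source_id = character()))
  expect_equal(empty$ll, c(AA = 0, AB = 0, BB = 0))
  expect_equal(empty$n_obs, 0L)

  one <- block_likelihoods(data.frame(allele = "MAJOR", error_prob = 0.001,
                                      source_id = "r1"))
  expect_equal(one$ll, c(AA = log10(0.999), AB = log10(0.5),
                         BB = log10(0.001)))

  obs <- data.frame(allele = c("MAJOR", "MAJOR", "MINOR"),
                    error_prob = c(0.01, 0.01, 0.01),
                    source_id = c("r1", "r2", "r3"))
  bl <- block_likelihoods(obs)
  for (g in c("AA", "AB", "BB")) {
    brute <- prod(observation_likelihood(obs$allele, obs$error_prob,
                                         rep(g, 3)))
    expect_equal(bl$ll[[g]], log10(brute), tolerance = 1e-12)
  }
  expect_equal(bl$n_obs, 3L)

  dup <- obs; dup$source_id <- c("r1", "r1", "r3")
  expect_error(block_likelihoods(dup), "source_id")
})

test_that("likelihoods factorize over disjoint observation sets", {
  set.seed(11)
  mk <- function(n, prefix) data.frame(
    allele = sample(c("MAJOR", "MINOR"), n, replace = TRUE),
    error_prob = runif(n, 1e-4, 0.4),
    source_id = paste0(prefix, seq_len(n)))
  o1 <- mk(7, "a"); o2 <- mk(5, "b")
  expect_equal(block_likelihoods(rbind(o1, o2))$ll,
               block_likelihoods(o1)$ll + block_likelihoods(o2)$ll,
               tolerance = 1e-12)
})

test_that("read and base filters follow the strict published bounds", {
  m <- toy_map()
  seq_at <- function(base) paste0("TT", base, "TT")  # SNP at offset 3
  r <- function(...) make_read(...)

  # mapping quality exactly 20 is excluded (strictly greater required)
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), mapq = 20L), m)), 0L)
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), mapq = 21L), m)), 1L)

  # base quality 19 excluded, 20 included (inclusive bound)
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), bq = 19L), m)), 0L)
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), bq = 20L), m)), 1L)

  # duplicate and secondary flags
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), flag = 0x400), m)), 0L)
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), flag = 0x100), m)), 0L)
  relaxed <- read_filter_config(exclude_duplicates = FALSE)
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), flag = 0x400), m, relaxed)), 1L)

  # unmapped-only input: empty result, not an error
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("A"), flag = 0x4), m)), 0L)

  # N or a third allele at the site is skipped
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("N")), m)), 0L)
  expect_equal(nrow(extract_observations(
    r("q1", "chr1", 98, seq_at("C")), m)), 0L)
})

test_that("filter monotonicity: raising min_base_quality never adds observations", {
  w <- small_world(n_blocks = 20, n_haplotypes = 100, seed = 31)
  ind <- sample_individual(w$panel, id = "X", seed = 1)
  reads <- simulate_reads(ind, w$map, assay_model(depth_lambda = 8,
                                                  frac_low_bq = 0.3), seed = 2)
  counts <- vapply(c(0L, 10L, 20L, 31L), function(q) {
    nrow(extract_observations(reads, w$map,
                              read_filter_config(min_base_quality = q)))
  }, integer(1))
  expect_false(is.unsorted(rev(counts)))
  expect_lt(counts[4], counts[1])  # BQ-31 bound actually bites (emitted BQ 30)
})

test_that("evidence is translated through member phase to anchor alleles", {
  m <- toy_map()
  # rs3 is a '-'-phased member of rs1: its major (G) is evidence for the
  # anchor's MINOR allele
  obs <- extract_observations(make_read("q1", "chr1", 398, "TTGTT"), m)
  expect_equal(obs$anchor, "rs1")
  expect_equal(obs$allele, "MINOR")
  obs2 <- extract_observations(make_read("q2", "chr1", 398, "TTATT"), m)
  expect_equal(obs2$allele, "MAJOR")  # rs3 minor -> anchor major
  # '+'-phased member rs2: major (C) -> MAJOR
  obs3 <- extract_observations(make_read("q3", "chr1", 248, "TTCTT"), m)
  expect_equal(obs3$allele, "MAJOR")
})

test_that("a read-pair yields at most one observation across the whole map", {
  m <- toy_map()
  # one read covering rs1 (pos 100) and rs2 (pos 250) would need length 151;
  # use a pair instead: mate1 over rs1, mate2 over rs2 (same block)
  pair <- rbind(make_read("q1", "chr1", 98, "TTATT"),
                make_read("q1", "chr1", 248, "TTCTT"))
  obs <- extract_observations(pair, m)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$anchor, "rs1")

  # mates over two *different* blocks: still one observation (first site in
  # coordinate order wins)
  pair2 <- rbind(make_read("q2", "chr2", 98, "TTTTT"),
                 make_read("q2", "chr1", 98, "TTATT"))
  obs2 <- extract_observations(pair2, m)
  expect_equal(nrow(obs2), 1L)
  expect_equal(obs2$anchor, "rs1")

  # one long read spanning both SNPs of a block: one observation
  long <- make_read("q3", "chr1", 50, strrep("T", 250))
  substr(long$seq, 51, 51) <- "A"    # rs1 at pos 100
  substr(long$seq, 201, 201) <- "C"  # rs2 at pos 250
  expect_equal(nrow(extract_observations(long, m)), 1L)
})

test_that("overlapping mates at one site merge or cancel", {
  m <- toy_map()
  # agreeing mates: one observation, higher-BQ base used
  agree <- rbind(make_read("q1", "chr1", 98, "TTATT", bq = 25L),
                 make_read("q1", "chr1", 96, "TTTTATT", bq = 35L))
  obs <- extract_observations(agree, m)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$error_prob, 10^(-3.5), tolerance = 1e-9)

  # disagreeing mates: the pair is discarded at that site
  clash <- rbind(make_read("q1", "chr1", 98, "TTATT"),
                 make_read("q1", "chr1", 96, "TTTTGTT"))
  expect_equal(nrow(extract_observations(clash, m)), 0L)
})

test_that("error probabilities come from Phred quality, clamped", {
  m <- toy_map()
  obs <- extract_observations(make_read("q1", "chr1", 98, "TTATT", bq = 30L), m)
  expect_equal(obs$error_prob, 1e-3)
  # clamp at the information-free bound for terrible bases
  lax <- read_filter_config(min_base_quality = 0L)
  obs2 <- extract_observations(make_read("q1", "chr1", 98, "TTATT", bq = 2L),
                               m, lax)
  expect_equal(obs2$error_prob, 0.5)
})

test_that("CIGARs with indels and clips are walked correctly", {
  m <- toy_map()
  # 2S then 2M starting at 99, so rs1 (pos 100) is query position 4
  read <- make_read("q1", "chr1", 99, "GGTA", cigar = "2S2M")
  obs <- extract_observations(read, m)
  expect_equal(obs$allele, "MAJOR")
  # deletion spanning the SNP: no observation
  del <- make_read("q2", "chr1", 98, "TTTT", cigar = "2M3D2M")
  expect_equal(nrow(extract_observations(del, m)), 0L)
  # insertion before the SNP shifts the query offset
  ins <- make_read("q3", "chr1", 98, "TTGGATT", cigar = "2M2I3M")
  obs3 <- extract_observations(ins, m)
  expect_equal(obs3$allele, "MAJOR")
})

test_that("build_fingerprint keeps empty blocks and recovers planted truth", {
  w <- small_world(n_blocks = 40, n_haplotypes = 200, seed = 53)
  fp0 <- build_fingerprint(NULL, w$map, sample_id = "empty")
  expect_equal(nrow(fp0$blocks), nrow(map_anchors(w$map)))
  expect_true(all(fp0$blocks$n_obs == 0L))
  expect_true(all(as.matrix(fp0$blocks[, 2:4]) == 0))

  # individual homozygous for the anchor-major haplotype at every block;
  # negative-phase members carry their own minor allele on that haplotype
  hval <- as.integer(w$map$phase[match(w$panel$snps$name, w$map$name)] == "-")
  hom <- structure(list(id = "hom",
                        hap = matrix(rep(hval, each = 2), 2,
                                     dimnames = list(NULL, w$panel$snps$name))),
                   class = "sim_individual")
  reads <- simulate_reads(hom, w$map,
                          assay_model(depth_lambda = 30,
                                      base_error_rate = 0.001), seed = 9)
  fp <- build_fingerprint(reads, w$map, sample_id = "hom")
  covered <- fp$blocks$n_obs > 0L
  expect_true(all(covered))
  amax <- max.col(as.matrix(fp$blocks[, 2:4]))
  expect_true(all(amax[covered] == 1L))
})

test_that("fingerprints add over disjoint halves of a read set", {
  w <- small_world(n_blocks = 25, n_haplotypes = 100, seed = 67)
  ind <- sample_individual(w$panel, id = "X", seed = 4)
  reads <- simulate_reads(ind, w$map, assay_model(depth_lambda = 10), seed = 5)
  half <- seq_len(nrow(reads)) %% 2 == 0
  f_all <- build_fingerprint(reads, w$map, sample_id = "all")
  f1 <- build_fingerprint(reads[half, ], w$map, sample_id = "h1")
  f2 <- build_fingerprint(reads[!half, ], w$map, sample_id = "h2")
  expect_equal(as.matrix(f_all$blocks[, 2:4]),
               as.matrix(f1$blocks[, 2:4]) + as.matrix(f2$blocks[, 2:4]),
               tolerance = 1e-9)
  expect_equal(f_all$blocks$n_obs, f1$blocks$n_obs + f2$blocks$n_obs)
})

test_that("VCF round trip preserves likelihoods and handles odd inputs", {
  w <- small_world(n_blocks = 100, n_haplotypes = 100, seed = 71)
  ind <- sample_individual(w$panel, id = "X", seed = 6)
  reads <- simulate_reads(ind, w$map, assay_model(depth_lambda = 6), seed = 7)
  fp <- build_fingerprint(reads, w$map, sample_id = "roundtrip")
  path <- withr::local_tempfile(fileext = ".vcf")
  fingerprint_to_vcf(fp, w$map, path)
  fp2 <- vcf_to_fingerprint(path, w$map)
  expect_equal(fp2$sample_id, "roundtrip")
  expect_lt(max(abs(as.matrix(fp$blocks[, 2:4]) - as.matrix(fp2$blocks[, 2:4]))),
            1e-6)
  expect_equal(fp2$blocks$n_obs, fp$blocks$n_obs)

  # records removed from the VCF become no-observation blocks
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  dropped_id <- strsplit(body[[1]], "\t")[[1]][3]
  writeLines(c(lines[startsWith(lines, "#")], body[-1]), path)
  fp3 <- vcf_to_fingerprint(path, w$map)
  i <- match(dropped_id, fp3$blocks$anchor)
  expect_equal(fp3$blocks$n_obs[i], 0L)
  expect_equal(unlist(fp3$blocks[i, 2:4]), c(ll_AA = 0, ll_AB = 0, ll_BB = 0))

  # extra non-map records are ignored with a message
  writeLines(c(lines, "chrZ\t1\tnot_in_map\tA\tC\t.\t.\tNOBS=1\tGT:GL\t0/0:0,0,0"),
             path)
  expect_message(fp4 <- vcf_to_fingerprint(path, w$map), "1 VCF record")
  expect_equal(as.matrix(fp4$blocks[, 2:4]), as.matrix(fp2$blocks[, 2:4]))

  # checksum binding: a different map refuses both directions
  other <- small_world(n_blocks = 100, n_haplotypes = 100, seed = 72)$map
  expect_error(vcf_to_fingerprint(path, other), "checksum")
  expect_error(fingerprint_to_vcf(fp, other, path), "checksum")
})

test_that("SAM writing and reading round-trips read sets", {
  w <- small_world(n_blocks = 10, n_haplotypes = 100, seed = 81)
  ind <- sample_individual(w$panel, id = "X", seed = 8)
  reads <- simulate_reads(ind, w$map, assay_model(depth_lambda = 5,
                                                  frac_duplicate = 0.2), seed = 9)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, path)
  back <- read_sam(path)
  expect_equal(back, reads)
  fp1 <- build_fingerprint(reads, w$map, sample_id = "a")
  fp2 <- build_fingerprint(read_alignments(path), w$map, sample_id = "a")
  expect_equal(fp1$blocks, fp2$blocks)
})
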
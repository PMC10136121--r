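test_that("exact matches score as the sum of BLOSUM62 diagonal entries", {
  g <- global_align("MKV", "MKV")
  expect_equal(g$score, 14)  # M 5 + K 5 + V 4
  expect_equal(g$aligned_ref, "MKV")
  expect_equal(g$aligned_target, "MKV")

  l <- local_align("AAAMKVAAA", "MKV")
  expect_equal(l$score, 14)
  expect_equal(l$ref_span, c(4L, 6L))
  expect_equal(l$target_span, c(1L, 3L))
})

test_that("self-alignment is the gapless identity", {
  set.seed(12)
  for (k in 1:10) {
    x <- random_protein_str(sample(1:40, 1))
    g <- global_align(x, x)
    expect_equal(g$aligned_ref, x)
    expect_equal(g$aligned_target, x)
    expect_false(grepl("-", g$aligned_ref, fixed = TRUE))
  }
})

test_that("a local alignment with no positive-scoring pair is empty", {
  # W vs G scores -2 under BLOSUM62; no positive cell anywhere
  l <- local_align("WWW", "GGG")
  expect_equal(l$score, 0)
  expect_equal(l$aligned_ref, "")
  expect_true(is.na(l$ref_span[1]))
  expect_equal(map_positions(l), setNames(integer(0), character(0)))
})

test_that("invalid residues are reported with symbol and position", {
  expect_error(global_align("MK1V", "MKV"), "'1' at position 3",
               class = "rq_usage_error")
  expect_error(local_align("MKV", "MKOV"), "'O' at position 3",
               class = "rq_usage_error")
  expect_error(six_frame_translate("ACGU"), "'U' at position 4",
               class = "rq_usage_error")
})

test_that("gap parameter contracts are enforced", {
  expect_error(align_params(gap_open = -1, gap_extend = -2),
               class = "rq_usage_error")
  expect_error(align_params(gap_extend = 0), class = "rq_usage_error")
})

test_that("DP scores match exhaustive enumeration on short random pairs", {
  bm <- rqscreen:::blosum62()
  set.seed(11)
  aa <- rownames(bm)[1:20]
  for (k in 1:30) {
    a <- paste(sample(aa, sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:8, 1), TRUE), collapse = "")
    for (loc in c(FALSE, TRUE)) {
      dp <- if (loc) local_align(a, b) else global_align(a, b)
      expect_equal(dp$score,
                   rqscreen:::.brute_best_score(a, b, bm, -11, -1, loc),
                   info = sprintf("%s vs %s (%s)", a, b,
                                  if (loc) "local" else "global"))
    }
  }
})

test_that("every alignment's score is recomputable from its gapped strings", {
  set.seed(13)
  for (k in 1:20) {
    a <- random_protein_str(sample(3:30, 1))
    b <- random_protein_str(sample(3:30, 1))
    p <- align_params()
    g <- global_align(a, b, p)
    expect_equal(alignment_score(g, p), g$score)
    l <- local_align(a, b, p)
    if (!is.na(l$ref_span[1])) expect_equal(alignment_score(l, p), l$score)
  }
})

test_that("position maps follow gaps and stay strictly increasing", {
  expect_equal(map_positions(global_align("MKV", "MKV")),
               setNames(1:3, 1:3))
  expect_equal(map_positions(global_align("MKV", "MV")),
               setNames(c(1L, NA, 2L), 1:3))
  set.seed(14)
  for (k in 1:10) {
    a <- random_protein_str(30); b <- random_protein_str(25)
    pm <- map_positions(global_align(a, b))
    mapped <- pm[!is.na(pm)]
    expect_true(all(diff(mapped) > 0))
  }
})

test_that("six-frame translation follows the standard code and stops", {
  fwd <- six_frame_translate("ATGGCC")
  expect_equal(fwd$peptide[fwd$frame == 1], "MA")
  rev <- six_frame_translate("GGCCAT")
  expect_equal(rev$peptide[rev$frame == -1], "MA")
  split <- six_frame_translate("ATGTAAATG")
  expect_equal(split$peptide[split$frame == 1], c("M", "M"))
  expect_equal(split$nt_start[split$frame == 1], c(1L, 7L))
  # N translates to X
  withN <- six_frame_translate("ATGAAN")
  expect_equal(withN$peptide[withN$frame == 1], "MX")
})

test_that("frame -k of a sequence equals frame +k of its reverse complement", {
  set.seed(15)
  for (k in 1:10) {
    nt <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
                collapse = "")
    a <- six_frame_translate(nt)
    b <- six_frame_translate(reverse_complement(nt))
    for (f in 1:3) {
      expect_equal(a$peptide[a$frame == -f], b$peptide[b$frame == f])
      expect_equal(b$peptide[b$frame == -f], a$peptide[a$frame == f])
    }
  }
})

test_that("planted residues are recovered through the position map under noise", {
  cfg_sub <- sim_config(seed = 0, substitution_rate = 0.02, indel_rate = 0,
                        n_decoys = 0)
  ref <- ref_set[["TDO2"]]
  pos <- 133L
  n_sub <- 0L
  for (r in 1:50) {
    cfg <- cfg_sub; cfg$seed <- 500L + r
    hom <- rqscreen:::with_seed(cfg$seed,
      rqscreen:::mutate_homolog(ref, pos, cfg))
    pm <- map_positions(global_align(ref, hom))
    tgt <- strsplit(hom, "")[[1]]
    if (!is.na(pm[[as.character(pos)]]) &&
        tgt[pm[[as.character(pos)]]] == "P") n_sub <- n_sub + 1L
  }
  expect_equal(n_sub, 50L)  # substitution-only noise never loses the site

  cfg_ind <- sim_config(seed = 0, substitution_rate = 0.02, indel_rate = 0.005,
                        n_decoys = 0, protect_window = 2)
  n_ind <- 0L
  for (r in 1:50) {
    cfg <- cfg_ind; cfg$seed <- 900L + r
    hom <- rqscreen:::with_seed(cfg$seed,
      rqscreen:::mutate_homolog(ref, pos, cfg))
    pm <- map_positions(global_align(ref, hom))
    tgt <- strsplit(hom, "")[[1]]
    if (!is.na(pm[[as.character(pos)]]) &&
        tgt[pm[[as.character(pos)]]] == "P") n_ind <- n_ind + 1L
  }
  expect_gte(n_ind, 48L)  # >= 95% with sparse indels outside the window
})
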
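test_that("the default panel carries the five published diagnostic sites", {
  panel <- default_panel()
  expect_named(panel, c("COQ2", "MEV1", "TDO2", "ETFDH"))
  expect_equal(panel$COQ2$sites$position, c(204L, 243L))
  expect_equal(panel$COQ2$sites$anaerobic_residue, c("L", "S"))
  expect_equal(panel$MEV1$sites$position, 71L)
  expect_equal(panel$MEV1$sites$anaerobic_residue, "G")
  expect_equal(panel$TDO2$sites$anaerobic_residue, "P")
  expect_equal(panel$ETFDH$sites$position, 437L)
  expect_equal(panel$ETFDH$sites$anaerobic_residue, "F")
  expect_equal(panel$COQ2$reference_accession, "NP_871684.1")
  expect_length(panel_site_labels(panel), 5L)
})

test_that("a reference sequence shorter than its sites is rejected", {
  expect_error(default_panel(list(COQ2 = random_protein_str(100))),
               "shorter than its largest site position",
               class = "rq_usage_error")
})

test_that("find_homolog picks the exact copy out of decoys", {
  set.seed(21)
  proteome <- data.frame(
    id = c(sprintf("decoy%02d", 1:20), "target"),
    description = "",
    sequence = c(vapply(sample(100:400, 20, TRUE), random_protein_str, ""),
                 ref_set[["MEV1"]]),
    stringsAsFactors = FALSE)
  hit <- find_homolog(ref_panel$MEV1, proteome)
  expect_s3_class(hit, "homolog_hit")
  expect_equal(hit$target_id, "target")
  expect_equal(hit$identity, 1)
  expect_equal(hit$coverage, 1)
})

test_that("decoy-only proteomes and empty proteomes give no hit", {
  set.seed(22)
  decoys <- data.frame(id = sprintf("d%02d", 1:10), description = "",
                       sequence = vapply(rep(200, 10), random_protein_str, ""),
                       stringsAsFactors = FALSE)
  expect_null(find_homolog(ref_panel$TDO2, decoys))
  expect_warning(res <- find_homolog(ref_panel$TDO2, decoys[0, ]),
                 "empty proteome")
  expect_null(res)
})

test_that("call_sites reads matches, variants and gap-induced missingness", {
  marker <- ref_panel$COQ2
  ref <- marker$reference_sequence
  # identity target: both sites match
  hit <- find_homolog(marker, data.frame(id = "t", description = "",
                                         sequence = ref))
  calls <- call_sites(marker, hit)
  expect_equal(calls$state, rep("ANAEROBIC_MATCH", 2))

  # Hydra-like COQ2: L kept at 204, A substituted at 243
  ch <- strsplit(ref, "")[[1]]
  ch[243] <- "A"
  hit2 <- find_homolog(marker, data.frame(id = "t", description = "",
                                          sequence = paste(ch, collapse = "")))
  calls2 <- call_sites(marker, hit2)
  expect_equal(calls2$state, c("ANAEROBIC_MATCH", "VARIANT"))
  expect_equal(calls2$observed, c("L", "A"))

  # deletion spanning site 204 -> MISSING there
  del <- paste(ch[-(200:208)], collapse = "")
  hit3 <- find_homolog(marker, data.frame(id = "t", description = "",
                                          sequence = del))
  calls3 <- call_sites(marker, hit3)
  expect_equal(calls3$state[1], "MISSING")

  # no hit at all -> everything MISSING
  expect_equal(call_sites(marker, NULL)$state, rep("MISSING", 2))
})

test_that("species classification follows the count rules and ignores order", {
  mk_calls <- function(states) {
    labels <- panel_site_labels(default_panel())
    data.frame(marker = sub(":.*", "", labels), site = labels,
               position = as.integer(sub(".*:", "", labels)),
               anaerobic_residue = "X", observed = "X", state = states,
               stringsAsFactors = FALSE)
  }
  full <- classify_species(mk_calls(rep("ANAEROBIC_MATCH", 5)))
  expect_equal(full$classification, "FULL_SIGNATURE")
  expect_equal(unname(full$counts), c(5L, 0L, 0L))

  none <- classify_species(mk_calls(rep("VARIANT", 5)))
  expect_equal(none$classification, "NO_SIGNATURE")

  insuf <- classify_species(mk_calls(rep("MISSING", 5)))
  expect_equal(insuf$classification, "INSUFFICIENT_DATA")

  mixed <- mk_calls(c("ANAEROBIC_MATCH", "VARIANT", "MISSING", "VARIANT",
                      "ANAEROBIC_MATCH"))
  part <- classify_species(mixed)
  expect_equal(part$classification, "PARTIAL_SIGNATURE")
  shuffled <- classify_species(mixed[c(3, 5, 1, 2, 4), ])
  expect_equal(shuffled$classification, part$classification)
  expect_equal(shuffled$counts, part$counts)

  expect_error(classify_species(mixed[1:4, ]), class = "rq_usage_error")
})

test_that("screening a synthetic proteome recovers the planted genotype", {
  sim <- make_proteome(genotype_anaerobic(),
                       sim_config(seed = 71, substitution_rate = 0,
                                  n_decoys = 15), ref_set)
  scr <- screen_proteome(ref_panel, sim$records, species = "synthetic")
  expect_equal(scr$profile$classification, "FULL_SIGNATURE")
  expect_equal(unname(scr$row),
               unname(genotype_anaerobic()[names(scr$row)]))

  sim2 <- make_proteome(genotype_aerobic(),
                        sim_config(seed = 72, substitution_rate = 0,
                                   n_decoys = 15), ref_set)
  scr2 <- screen_proteome(ref_panel, sim2$records)
  expect_equal(scr2$profile$classification, "NO_SIGNATURE")
})

test_that("the protein and six-frame nucleotide routes agree", {
  g <- genotype_from_binary(c(TRUE, FALSE, TRUE, TRUE, FALSE))
  sim <- make_proteome(g, sim_config(seed = 73, substitution_rate = 0.01,
                                     n_decoys = 0), ref_set)
  prot <- screen_proteome(ref_panel, sim$records)
  contigs <- do.call(rbind, lapply(seq_len(nrow(sim$records)), function(i)
    make_contig(sim$records$sequence[i],
                strand = c("+", "-")[i %% 2 + 1],
                frame_offset = i %% 3, seed = 80 + i,
                id = paste0("ctg", i))))
  nuc <- screen_proteome(ref_panel, contigs, type = "nucleotide")
  expect_equal(nuc$profile$calls$state, prot$profile$calls$state)
  expect_equal(nuc$profile$classification, prot$profile$classification)
})

test_that("classifying the residue survey mirrors the published reading", {
  res <- classify_matrix(survey)
  cls <- vapply(res$profiles, `[[`, "", "classification")
  # exactly one cnidarian shows the full five-residue signature
  expect_equal(sum(cls[cnidarians] == "FULL_SIGNATURE"), 1L)
  expect_equal(names(which(cls[cnidarians] == "FULL_SIGNATURE")),
               "Nematostella vectensis")
  # no cnidarian is signature-free: all carry the ETFDH match
  expect_equal(sum(cls[cnidarians] == "NO_SIGNATURE"), 0L)
  expect_equal(unname(res$site_matches["ETFDH:437"]), 17L)  # all but human
  for (sp in cnidarians)
    expect_equal(res$profiles[[sp]]$calls$state[5], "ANAEROBIC_MATCH")
  # the references behave as expected
  expect_equal(cls[["Homo sapiens"]], "NO_SIGNATURE")
  expect_equal(cls[["Caenorhabditis elegans"]], "FULL_SIGNATURE")
})

test_that("classify_matrix rejects mismatched sites and handles empty input", {
  bad <- survey
  colnames(bad)[1] <- "COQ2:999"
  expect_error(classify_matrix(bad), "do not match the panel",
               class = "rq_usage_error")
  empty <- classify_matrix(survey[0, , drop = FALSE])
  expect_length(empty$profiles, 0L)
  expect_equal(sum(empty$summary), 0L)
})
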
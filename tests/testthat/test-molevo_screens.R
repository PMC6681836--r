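test_that("identical coding sequences give Ka = Ks = 0, ratio undefined", {
  cds <- "ATGGCTAAGGGATTA"
  res <- ng86_kaks(cds, cds)
  expect_equal(res$ka, 0)
  expect_equal(res$ks, 0)
  expect_false(res$ratio_defined)
  expect_true(is.na(res$ratio))
})

test_that("site counts satisfy N + S = 3 x codons and match hand counting", {
  # GGA (Gly): all 3 third-position changes synonymous; positions 1-2 all
  # nonsynonymous; no stop-codon exclusions -> S = 1 exactly
  expect_equal(tpsurvey:::ng86_codon_sites("GGA"), 1)
  # ATG (Met): no synonymous change at any position
  expect_equal(tpsurvey:::ng86_codon_sites("ATG"), 0)
  # TTA (Leu): pos1 TTA->CTA syn (1/3); pos3 TTA->TTG syn, TAA/TGA are
  # stops so pos2 has one excluded change (TCA, TGA-> stop excluded)
  # hand count: pos1: CTA syn, ATA ile, GTA val -> 1/3
  #             pos2: TCA ser, TAA stop (excluded), TGA stop (excluded) -> 0/1
  #             pos3: TTG syn, TTT phe, TTC phe -> 1/3
  expect_equal(tpsurvey:::ng86_codon_sites("TTA"), 1 / 3 + 0 + 1 / 3)
  set.seed(8)
  code <- tpsurvey:::genetic_code()
  sense <- names(code)[code != "*"]
  for (i in 1:25) {
    n <- sample(5:30, 1)
    a <- paste(sample(sense, n, replace = TRUE), collapse = "")
    b <- paste(sample(sense, n, replace = TRUE), collapse = "")
    res <- ng86_kaks(a, b)
    expect_equal(res$n + res$s, 3 * n, tolerance = 1e-9)
  }
})

test_that("a single synonymous third-position change gives Ka = 0, Ks > 0", {
  base <- strrep("ATGGCTAAG", 33)            # 99 codons
  a <- paste0(base, "GGA")
  b <- paste0(base, "GGG")                   # Gly -> Gly
  res <- ng86_kaks(a, b)
  expect_equal(res$ka, 0)
  expect_gt(res$ks, 0)
  expect_equal(res$sd, 1)
  expect_equal(res$nd, 0)
  # oracle: p_s = 1/S, Ks = JC(p_s)
  expect_equal(res$ks, -3 / 4 * log(1 - 4 * (1 / res$s) / 3))
})

test_that("two-difference codons average over enumerated pathways", {
  # TTT (Phe) vs GTA (Val): differs at positions 1 and 3
  # path 1: TTT -> GTT (Phe->Val, nonsyn) -> GTA (Val->Val, syn)
  # path 2: TTT -> TTA (Phe->Leu, nonsyn) -> GTA (Leu->Val, nonsyn)
  # average: Sd = (1 + 0)/2 = 0.5, Nd = (1 + 2)/2 = 1.5
  d <- tpsurvey:::ng86_codon_diffs("TTT", "GTA")
  expect_equal(unname(d["sd"]), 0.5)
  expect_equal(unname(d["nd"]), 1.5)
  # within ng86_kaks on a padded sequence
  base <- strrep("ATGGCTAAG", 20)
  res <- ng86_kaks(paste0(base, "TTT"), paste0(base, "GTA"))
  expect_equal(res$sd, 0.5)
  expect_equal(res$nd, 1.5)
})

test_that("gapped codons are dropped pairwise; frame errors are caught", {
  res <- ng86_kaks("ATG---GGA", "ATGGCTGGG")
  expect_equal(res$n_codons, 2)
  expect_error(ng86_kaks("ATGG", "ATGG"), "divisible")
  expect_error(ng86_kaks("ATGTAAGGA", "ATGTACGGA"), "stop")
})

test_that("NG86 recovers a simulated dN/dS within 15%", {
  # single-pair estimates at 1000 codons scatter ~12% (simulation noise
  # dominates), so recovery is asserted on the mean over replicate pairs
  ratios <- vapply(1:5, function(s) {
    sim <- simulate_codon_pair(n_codons = 1000, omega = 0.5,
                               n_proposals = 500, seed = s)
    res <- ng86_kaks(sim$cds_a, sim$cds_b)
    expect_true(res$ratio_defined)
    res$ratio
  }, 0)
  expect_lt(abs(mean(ratios) - 0.5) / 0.5, 0.15)
})

test_that("back-translation threads codons through the protein alignment", {
  cds <- "ATGGCTAAG"
  expect_identical(back_translate("MAK", cds), "ATGGCTAAG")
  expect_identical(back_translate("M-AK", cds), "ATG---GCTAAG")
  expect_identical(back_translate("MAK", paste0(cds, "TAA")), "ATGGCTAAG")
  expect_error(back_translate("MAKR", cds), "match")
})

test_that("percentages use exact ratios with half-up rounding", {
  expect_equal(percent_of(948, 1054), 89.9)
  expect_equal(percent_of(20113, 22375), 89.9)
  expect_equal(percent_of(9, 30), 30.0)
  expect_equal(percent_of(0, 103), 0.0)
  expect_equal(round_half_up(0.25, 1), 0.3)   # plain round() gives 0.2
  expect_equal(round_half_up(89.85, 1), 89.9)
})

test_that("PPD seeds are discovered at the relaxed cutoff and deduplicated", {
  p <- fix_calibrated_small()
  inst <- sample_domain_instance(p, 0.05, seed = 301)
  decoys <- with_seed(303, setNames(
    vapply(1:18, function(i) tpsurvey:::random_protein(140), ""),
    sprintf("ids_bg%02d", 1:18)))
  # shrink the planted fragment until it straddles the two thresholds:
  # absent at E <= 1, recovered at E <= 100 (fixture found by search)
  found <- NULL
  for (keep in seq(20, 6, by = -2)) {
    frag <- substr(inst, 5, 4 + keep)
    ids_set <- with_seed(302, tps_seqs(c(
      ids1 = paste0(tpsurvey:::random_protein(60), frag,
                    tpsurvey:::random_protein(60)),
      ids2 = paste0(tpsurvey:::random_protein(55), frag,
                    tpsurvey:::random_protein(65)),
      decoys)))
    strict <- discover_ppd(ids_set, p, relaxed_e = 1)
    relaxed <- discover_ppd(ids_set, p, relaxed_e = 100)
    if (!any(c("ids1", "ids2") %in% strict$hits$seq_id) &&
        all(c("ids1", "ids2") %in% relaxed$hits$seq_id)) {
      found <- relaxed
      break
    }
  }
  expect_false(is.null(found))
  expect_lte(found$n_unique, found$n_raw)
  # two identical proteins give identical envelopes: one unique seed
  twin <- with_seed(304, paste0(tpsurvey:::random_protein(50),
                                substr(inst, 1, 30),
                                tpsurvey:::random_protein(50)))
  twins <- tps_seqs(c(t1 = twin, t2 = twin))
  res_tw <- discover_ppd(twins, p, relaxed_e = 100)
  expect_true(all(c("t1", "t2") %in% res_tw$hits$seq_id))
  expect_identical(res_tw$n_raw - res_tw$n_unique >= 1, TRUE)
})

test_that("PPD reports carry exact percentages per scanned set", {
  p <- fix_calibrated_small()
  planted <- function(seed) {
    with_seed(seed, paste0(tpsurvey:::random_protein(30),
                           sample_domain_instance(p, 0.1, seed = seed + 1),
                           tpsurvey:::random_protein(30)))
  }
  bg <- function(n, seed) with_seed(seed, setNames(
    vapply(seq_len(n), function(i) tpsurvey:::random_protein(150), ""),
    sprintf("bg%d_%02d", seed, seq_len(n))))
  sets <- list(
    with_hits = tps_seqs(c(a1 = planted(311), a2 = planted(313),
                           bg(8, 315))),
    without = tps_seqs(bg(10, 317)))
  # cutoff 0.5: the planted sequences score E ~0.05-0.13 while every
  # background sequence in these fixed sets scores E > 0.8
  rep <- ppd_scan_report(p, sets, e_cutoff = 0.5)
  expect_identical(rep$set, c("with_hits", "without"))
  expect_equal(rep$percentage[1], 20.0)   # 2 of 10, exact then rounded
  expect_equal(rep$percentage[2], 0.0)
  expect_error(ppd_scan_report(p, list(empty = tps_seqs(c(x = "MK"))[0])),
               "empty")
})

test_that("conserved columns honor thresholds and row subsets", {
  msa <- multiple_alignment(c(
    ids1 = "WKDAY",
    ids2 = "WKDAY",
    tps1 = "WKDTY",
    tps2 = "WKD-Y"))
  expect_identical(conserved_columns(msa), c(1L, 2L, 3L, 5L))
  # column 4 is conserved within the IDS subset only
  expect_true(4L %in% conserved_columns(msa, subset = c("ids1", "ids2")))
  expect_false(4L %in% conserved_columns(msa))
  all_same <- multiple_alignment(c(a = "WWW", b = "WWW"))
  expect_identical(conserved_columns(all_same), 1:3)
  expect_error(conserved_columns(msa, identity_threshold = 0), "threshold")
  expect_error(conserved_columns(msa, subset = "nope"), "subset")
})

test_that("HGT verdicts follow the four-rule conjunction", {
  ok <- hgt_rules(best_identity = 0.95, best_coverage = 0.9,
                  n_plant_species_high = 3, n_other_bacteria_with_homolog = 0)
  expect_identical(ok$verdict, "HGT_candidate")
  expect_length(ok$failed_rules, 0)
  low_id <- hgt_rules(0.75, 0.9, 3, 0)
  expect_identical(low_id$verdict, "rejected")
  expect_identical(low_id$failed_rules, "identity")
  with_homolog <- hgt_rules(0.95, 0.9, 3, 1)   # 60% homolog elsewhere
  expect_identical(with_homolog$verdict, "rejected")
  expect_identical(with_homolog$failed_rules, "bacterial_homolog")
})

test_that("HGT rule engine equals brute-force predicate evaluation", {
  set.seed(404)
  for (i in 1:500) {
    id <- runif(1); cov <- runif(1)
    np <- sample(0:4, 1); nb <- sample(0:2, 1)
    got <- hgt_rules(id, cov, np, nb)$verdict == "HGT_candidate"
    want <- (cov > 0.70) && (id > 0.80) && (np >= 2) && (nb == 0)
    expect_identical(got, want)
  }
})

test_that("screen_hgt flags a transferred protein and rejects controls", {
  set.seed(420)
  tps_core <- rand_prot(180, 421)
  mutate <- function(s, rate, seed) with_seed(seed, {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(tpsurvey:::AA_ALPHABET20, a), 1), "")
    paste(ch, collapse = "")
  })
  plant_panels <- list(
    cotton = tps_seqs(c(cotton_tps = tps_core)),
    citrus = tps_seqs(c(citrus_tps = mutate(tps_core, 0.1, 422))),
    grape  = tps_seqs(c(grape_tps = mutate(tps_core, 0.12, 423))))
  other_bact <- list(
    nitro2 = tps_seqs(c(n2 = rand_prot(180, 424))),
    nitro3 = tps_seqs(c(n3 = rand_prot(180, 425))))
  queries <- tps_seqs(c(
    hgt_query = tps_core,                  # identical to the cotton protein
    diverged = mutate(tps_core, 0.35, 426),
    unrelated = rand_prot(180, 427)))
  res <- screen_hgt(queries, plant_panels, other_bact)
  expect_identical(res$verdict[res$query == "hgt_query"], "HGT_candidate")
  expect_gte(res$n_plant_species_high[res$query == "hgt_query"], 2)
  expect_identical(res$verdict[res$query == "unrelated"], "rejected")
  # a bacterial homolog at > 50% identity vetoes the call
  other_with_hom <- c(other_bact, list(nitro4 = tps_seqs(c(
    n4 = mutate(tps_core, 0.2, 428)))))
  res2 <- screen_hgt(queries, plant_panels, other_with_hom)
  expect_identical(res2$verdict[res2$query == "hgt_query"], "rejected")
  expect_match(res2$failed_rules[res2$query == "hgt_query"],
               "bacterial_homolog")
})
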
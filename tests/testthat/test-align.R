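test_that("an identical fragment aligns perfectly at stretch 1", {
  arm <- reference_arm("t1", seq(5000, 395000, by = 8000), 400000)
  frag <- arm$label_positions / 1000
  p <- align_params()
  a <- align_fragment(frag, arm, p)
  expect_equal(a$n_matched, length(frag))
  expect_equal(a$score, length(frag) * p$match_reward)
  expect_equal(a$stretch, 1)
})

test_that("the DP equals exhaustive monotone-matching enumeration", {
  p <- align_params(max_step = 8, ref_collapse_kb = 0)
  withr::local_seed(42)
  for (rep in 1:80) {
    inst <- random_align_instance()
    dp <- smtaom:::dp_score(inst$ref, inst$mol, inst$s, p)
    bf <- brute_force_score(inst$ref, inst$mol, inst$s, p)
    expect_equal(dp, bf, tolerance = 1e-10)
  }
})

test_that("a globally stretched fragment recovers its stretch factor", {
  arm <- reference_arm("t1", seq(5000, 395000, by = 7000), 400000)
  frag <- arm$label_positions / 1000 * 1.02
  a <- align_fragment(frag, arm)
  expect_gte(a$stretch, 1.015)
  expect_lte(a$stretch, 1.025)
  expect_equal(a$n_matched, length(frag))
})

test_that("alignment score is invariant under translation and mirroring", {
  p <- align_params(ref_collapse_kb = 0)
  withr::local_seed(7)
  for (rep in 1:20) {
    ref <- cumsum(runif(10, 3, 10))
    mol <- cumsum(runif(8, 3, 10))
    base <- smtaom:::dp_score(ref, mol, 1, p)
    shifted <- smtaom:::dp_score(ref + 123.4, mol + 77.7, 1, p)
    expect_equal(shifted, base, tolerance = 1e-9)
    mirror <- function(x) sort(max(x) + min(x) - x)
    mirrored <- smtaom:::dp_score(mirror(ref), mirror(mol), 1, p)
    expect_equal(mirrored, base, tolerance = 1e-9)
  }
})

test_that("adding a matchable label never decreases the optimal score", {
  p <- align_params(ref_collapse_kb = 0)
  withr::local_seed(19)
  for (rep in 1:30) {
    ref <- cumsum(runif(7, 3, 10))
    mol <- ref * 1.01 + 5
    base <- smtaom:::dp_score(ref, mol, 1.01, p)
    ext <- runif(1, 4, 9)
    grown <- smtaom:::dp_score(c(ref, max(ref) + ext),
                               c(mol, max(mol) + ext * 1.01), 1.01, p)
    expect_gte(grown, base)
  }
})

test_that("assignability floors force UNASSIGNED without errors", {
  rs <- tiny_refset(3)
  arm1 <- rs$arms[[1]]
  # a 3-label fragment cannot reach min_matched_labels = 9
  short <- structure(list(molecule_id = "s", length_kb = 40,
                          green_labels = c(5, 18, 30),
                          red_segments = data.frame(start_kb = numeric(0),
                                                    end_kb = numeric(0),
                                                    intensity = numeric(0)),
                          cohort = "t"), class = "smta_molecule")
  a <- assign_arms(short, rs)
  expect_true(all(a$arm_id == "UNASSIGNED"))

  # a duplicated reference arm kills the margin
  dup <- reference_set(list(
    reference_arm("1q", arm1$label_positions, arm1$terminus_pos),
    reference_arm("2q", arm1$label_positions, arm1$terminus_pos)))
  m <- make_end_tel_mol(arm1, L = 200, telo = 10)
  ad <- assign_arms(m, dup)
  expect_true(all(ad$arm_id == "UNASSIGNED"))
  expect_true(any(ad$qc == "below_floor"))
  expect_true(all(ad$margin < 0.01, na.rm = TRUE))

  # fragments with fewer than 2 labels are UNASSIGNED, never an exception
  bare <- structure(list(molecule_id = "b", length_kb = 30,
                         green_labels = 12,
                         red_segments = data.frame(start_kb = numeric(0),
                                                   end_kb = numeric(0),
                                                   intensity = numeric(0)),
                         cohort = "t"), class = "smta_molecule")
  ab <- assign_arms(bare, rs)
  expect_equal(ab$arm_id, "UNASSIGNED")
  expect_equal(ab$qc, "few_labels")
})

test_that("noisy end-telomere fragments are assigned to their true arm", {
  rs <- synthesize_reference(n_arms = 10, seed = 31)
  cfg <- sim_config(event_rates = c(end_tel = 1, tfe = 0, its_plus = 0,
                                    its_minus = 0),
                    molecules_per_arm = 12, seed = 32)
  sim <- simulate_cohort(rs, cfg, "acc")
  hits <- 0; assigned <- 0
  for (i in seq_along(sim$molecules)) {
    a <- assign_arms(sim$molecules[[i]], rs)
    a <- a[a$arm_id != "UNASSIGNED", , drop = FALSE]
    if (nrow(a)) {
      assigned <- assigned + 1
      hits <- hits + (a$arm_id[which.max(a$score)] == sim$truth$true_arm[i])
    }
  }
  expect_gte(assigned / length(sim$molecules), 0.9)
  expect_gte(hits / assigned, 0.95)
})
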
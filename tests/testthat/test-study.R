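sim_small <- simulate_cohort(simulation_config(seed = 30))
ann_regime <- data.frame(sample_id = names(sim_small$truth$regime),
                         label = unname(sim_small$truth$regime),
                         stringsAsFactors = FALSE)

test_that("stratified networks separate planted regimes", {
  cfg <- analysis_config(n_permutations = 300, master_seed = 30)
  out <- run_stratified_networks(sim_small$matrix, ann_regime,
                                 "low", "high", cfg)
  expect_gt(out$distance, 5)
  expect_equal(sum(out$n), 118)
  expect_identical(out$distance, out$distance_report$distance)
  # signs: the recovered low-regime module is positively signed
  expect_true(all(out$graphs$low$edges$sign == "positive"))
})

test_that("degenerate stratifications fail loudly", {
  cfg <- analysis_config(n_permutations = 100)
  expect_error(run_stratified_networks(sim_small$matrix, ann_regime,
                                       "low", "ER+", cfg),
               "no sample carries", class = "coregscan_validation_error")
  bad <- ann_regime
  bad$sample_id[1] <- "ghost"
  expect_error(run_stratified_networks(sim_small$matrix, bad,
                                       "low", "high", cfg), "ghost")
})

test_that("two random halves of one regime give a small distance", {
  sim <- simulate_cohort(simulation_preset("single-regime", seed = 31))
  set.seed(31)
  half <- sample(c("A", "B"), 118, replace = TRUE)
  ann <- data.frame(sample_id = sim$matrix$sample_ids, label = half)
  out <- run_stratified_networks(sim$matrix, ann, "A", "B",
                                 analysis_config(n_permutations = 300,
                                                 master_seed = 31))
  # both halves see the same co-regulation: most module edges match
  expect_lte(out$distance, 8)
})

test_that("the full study writes a complete, reproducible report bundle", {
  cfg <- analysis_config(n_permutations = 200, master_seed = 30)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  for (d in c(d1, d2)) {
    run_full_study(sim_small$matrix, "ERa36", cfg, out_dir = d,
                   annotation = ann_regime, label_a = "low",
                   label_b = "high", scan_n_permutations = 200)
  }
  expected <- c("manifest.json", "scan.json", "best_split_distance.json",
                "stratified_distance.json", "best_low.json", "best_high.json",
                "best_low.graphml", "best_high.dot", "best_low_stats.tsv",
                "stratified_low.json", "stratified_high_stats.tsv")
  expect_true(all(file.exists(file.path(d1, expected))))
  jsons <- setdiff(list.files(d1, pattern = "\\.json$"), "manifest.json")
  for (f in jsons) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # the manifest records the seed and every scan setting
  man <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_equal(man$master_seed, 30)
  expect_equal(man$scan$step, 0.5)
  expect_equal(man$scan$min_group_size, 12)
  expect_equal(man$config$n_permutations, 200)
})

test_that("the CLI drives simulate, infer, scan and distance end to end", {
  wd <- tempdir()
  cohort <- file.path(wd, "cohort.tsv")
  truth <- file.path(wd, "truth.json")
  expect_equal(cli_main(c("simulate", "--preset", "two-regime",
                          "--seed", "5", "--out", cohort,
                          "--truth", truth, "--quiet")), 0L)
  expect_true(file.exists(cohort) && file.exists(truth))
  tr <- jsonlite::fromJSON(truth)
  expect_equal(tr$planted_threshold, 8.5)

  prefix <- file.path(wd, "net")
  expect_equal(suppressMessages(
    cli_main(c("infer", "--in", cohort, "--out-prefix", prefix,
               "--permutations", "200", "--seed", "5", "--quiet"))), 0L)
  expect_true(file.exists(paste0(prefix, ".json")))
  expect_equal(cli_main(c("distance", "--a", paste0(prefix, ".json"),
                          "--b", paste0(prefix, ".json"), "--quiet")), 0L)

  scan_out <- file.path(wd, "scan.json")
  expect_equal(cli_main(c("scan", "--in", cohort, "--gene", "ERa36",
                          "--permutations", "150", "--seed", "5",
                          "--out", scan_out, "--quiet")), 0L)
  sc <- jsonlite::fromJSON(scan_out)
  expect_true(is.numeric(sc$best_threshold))

  # exit codes: 2 for input validation, 3 for statistical degeneracy
  expect_equal(suppressMessages(
    cli_main(c("scan", "--in", cohort, "--gene", "NOPE", "--quiet"))), 2L)
  expect_equal(suppressMessages(cli_main(c("nonsense"))), 2L)
  tiny <- file.path(wd, "tiny.tsv")
  cli_main(c("simulate", "--preset", "null", "--n-samples", "20",
             "--seed", "2", "--out", tiny, "--quiet"))
  expect_equal(suppressMessages(
    cli_main(c("scan", "--in", tiny, "--gene", "ERa36",
               "--permutations", "150", "--quiet"))), 3L)
})

test_that("CLI flags override configuration file values", {
  wd <- tempdir()
  cfgfile <- file.path(wd, "cfg.yaml")
  writeLines(c("alpha_mi: 0.05", "n_permutations: 150", "master_seed: 9"),
             cfgfile)
  cohort <- file.path(wd, "cfg_cohort.tsv")
  cli_main(c("simulate", "--seed", "9", "--out", cohort, "--quiet"))
  prefix <- file.path(wd, "cfg_net")
  expect_equal(suppressMessages(
    cli_main(c("infer", "--in", cohort, "--out-prefix", prefix,
               "--config", cfgfile, "--permutations", "200", "--quiet"))), 0L)
  stats <- read.delim(paste0(prefix, "_stats.tsv"))
  # permutations came from the flag (200), not the file (150):
  # every p is a multiple of 1/201 up to the table's print precision
  expect_true(all(stats$p_mi >= 1 / 201 - 1e-8))
  expect_true(all(abs(stats$p_mi * 201 - round(stats$p_mi * 201)) < 1e-4))
})
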
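test_that("risk-locus carrier draws are Bernoulli at group frequencies", {
  map <- tiny_map(300)
  base <- cohort_config(
    n_cases = 100, n_controls = 100, del_rate = 0, dup_rate = 0,
    risk_loci = list(risk_locus("L1", "1", 1.05e6, 1.15e6,
                                case_freq = 0.5, control_freq = 0)),
    common_loci = list(), qc_fail_frac = 0, family_frac = 0)
  carr <- matrix(0L, 200, 2)
  for (s in 1:200) {
    base$seed <- s
    ch <- generate_cohort(base, map)
    ids <- unique(ch$truth$sample_id)
    g <- ch$samples$group[match(ids, ch$samples$sample_id)]
    carr[s, ] <- c(sum(g == "case"), sum(g == "control"))
  }
  expect_true(all(carr[, 2] == 0))  # control frequency 0 -> no carriers
  # mean case carriers ~ Binomial(100, 0.5); 200-seed average within 5 se
  se <- sqrt(100 * 0.25 / 200)
  expect_lt(abs(mean(carr[, 1]) - 50), 5 * se)
  expect_gt(var(carr[, 1]), 0)  # different seeds give different cohorts
})

test_that("zero rates and no risk loci give an empty truth set", {
  map <- tiny_map(100)
  cfg <- noiseless_config()
  ch <- generate_cohort(cfg, map)
  expect_equal(nrow(ch$truth), 0)
})

test_that("study-scale carrier counts match the published frequencies", {
  # carrier frequencies 64/1614 cases and 18/3922 controls at the chr10
  # locus; one draw must fall inside the 99% binomial envelope
  map <- toy_marker_map(1000, spacing = 5000)
  cfg <- cohort_config(
    del_rate = 0, dup_rate = 0,
    risk_loci = list(risk_locus("chr10", "10", 47049547, 47703870,
                                case_freq = 64 / 1614,
                                control_freq = 18 / 3922)),
    common_loci = list(), qc_fail_frac = 0, family_frac = 0, seed = 99)
  ch <- generate_cohort(cfg, map)
  ids <- unique(ch$truth$sample_id)
  g <- ch$samples$group[match(ids, ch$samples$sample_id)]
  a <- sum(g == "case"); c_ <- sum(g == "control")
  expect_gte(a, qbinom(0.005, 1614, 64 / 1614))
  expect_lte(a, qbinom(0.995, 1614, 64 / 1614))
  expect_gte(c_, qbinom(0.005, 3922, 18 / 3922))
  expect_lte(c_, qbinom(0.995, 3922, 18 / 3922))
})

test_that("noise-free intensities reproduce the state means exactly", {
  map <- tiny_map(200)
  cfg <- noiseless_config()
  s <- list(sample_id = "s1", wf = 0)
  tr <- mk_call("s1", "1", map$pos[50], map$pos[99], 3)[
    , c("sample_id", "chrom", "start", "end", "copy_state")]
  tr$origin <- "background_rare"
  set.seed(5)
  prof <- simulate_intensities(s, tr, map, cfg)
  expect_equal(mean(prof$lrr[50:99]), 0.35)
  expect_equal(unique(prof$lrr[-(50:99)]), 0)
  # CN3 BAF clusters at 0, 1/3, 2/3, 1 only
  expect_true(all(prof$baf[50:99] %in% c(0, 1 / 3, 2 / 3, 1)))
})

test_that("single-copy deletions lose the heterozygote band", {
  map <- tiny_map(200)
  cfg <- noiseless_config()
  tr <- data.frame(sample_id = "s1", chrom = "1", start = map$pos[20],
                   end = map$pos[180], copy_state = 1L,
                   origin = "background_rare", stringsAsFactors = FALSE)
  set.seed(6)
  prof <- simulate_intensities(list(sample_id = "s1", wf = 0), tr, map, cfg)
  expect_false(any(prof$baf[20:180] > 0.2 & prof$baf[20:180] < 0.8))
})

test_that("waviness couples LRR to GC at the sample's wf", {
  map <- tiny_map(2000, gc = seq(0.3, 0.7, length.out = 2000))
  cfg <- cohort_config(lrr_sd = 0.18, baf_sd = 0.03, wave_gain = 1,
                       risk_loci = list(), common_loci = list(),
                       del_rate = 0, dup_rate = 0, n_cases = 2,
                       n_controls = 2, qc_fail_frac = 0, family_frac = 0)
  set.seed(7)
  prof <- simulate_intensities(list(sample_id = "s1", wf = 0.4),
                               truth = data.frame(sample_id = character(),
                                                  chrom = character(),
                                                  start = numeric(),
                                                  end = numeric(),
                                                  copy_state = integer(),
                                                  origin = character()),
                               map, cfg)
  expect_gt(cor(prof$lrr, map$gc), 0.5)
})

test_that("truth intervals without markers are rejected at simulation", {
  map <- tiny_map(100)
  cfg <- noiseless_config()
  tr <- data.frame(sample_id = "s1", chrom = "9", start = 1, end = 2,
                   copy_state = 3L, origin = "background_rare",
                   stringsAsFactors = FALSE)
  expect_error(
    simulate_intensities(list(sample_id = "s1", wf = 0), tr, map, cfg),
    "spans no markers")
})

test_that("fixtures are deterministic, atomic and round-trip their truth", {
  map <- tiny_map(400)
  cfg <- cohort_config(
    n_cases = 5, n_controls = 5, del_rate = 0.3, dup_rate = 0.3,
    del_total_mean = c(case = 9e3, control = 8e3),
    dup_total_mean = c(case = 9e3, control = 8e3),
    risk_loci = list(risk_locus("L1", "1", 1.1e6, 1.15e6, 0.5, 0.2)),
    common_loci = list(list(name = "c1", chrom = "1", start = 1.3e6,
                            end = 1.32e6, frequency = 0.2,
                            copy_state = 3L)),
    qc_fail_frac = 0, family_frac = 0, seed = 21)
  d1 <- file.path(withr::local_tempdir(), "fx1")
  d2 <- file.path(withr::local_tempdir(), "fx2")
  emit_fixture(d1, cfg, map)
  emit_fixture(d2, cfg, map)
  files <- c("markers.tsv", "samples.tsv", "truth.bed", "artifacts.bed",
             "common_cnv.bed", "genes.bed", "manifest.yaml")
  expect_true(all(file.exists(file.path(d1, files))))
  sigs <- list.files(file.path(d1, "signals"))
  expect_length(sigs, 10)
  # same seed -> byte-identical fixture
  for (f in c(files, file.path("signals", sigs))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # manifest records the seed; truth BED round-trips the generated truth
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$seed, 21)
  cohort <- generate_cohort(cfg, map)
  back <- read_truth_bed(file.path(d1, "truth.bed"))
  ord <- function(x) x[order(x$sample_id, x$chrom, x$start), ]
  expect_equal(ord(back), ord(cohort$truth), ignore_attr = TRUE)
  # different seed -> different truth
  cfg2 <- cfg; cfg2$seed <- 22L
  d3 <- file.path(withr::local_tempdir(), "fx3")
  emit_fixture(d3, cfg2, map)
  expect_false(identical(readLines(file.path(d1, "truth.bed")),
                         readLines(file.path(d3, "truth.bed"))))
  # refuses to overwrite
  expect_error(emit_fixture(d1, cfg, map), "already exists")
})

test_that("relatives share the index case's risk-locus carrier status", {
  map <- tiny_map(300)
  cfg <- cohort_config(
    n_cases = 40, n_controls = 10, del_rate = 0, dup_rate = 0,
    risk_loci = list(risk_locus("L1", "1", 1.05e6, 1.2e6, 0.5, 0)),
    common_loci = list(), qc_fail_frac = 0, family_frac = 0.4, seed = 31)
  ch <- generate_cohort(cfg, map)
  fams <- split(ch$samples$sample_id, ch$samples$family_id)
  expect_gt(length(fams), 0)
  for (members in fams) {
    carrier <- members %in% ch$truth$sample_id
    expect_true(all(carrier) || all(!carrier))
  }
  # keep_unrelated keeps exactly one member per family
  kept <- keep_unrelated(ch$samples)
  kf <- kept$family_id[!is.na(kept$family_id)]
  expect_false(any(duplicated(kf)))
  expect_equal(sort(unique(kf)), sort(unique(ch$samples$family_id[
    !is.na(ch$samples$family_id)])))
})
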
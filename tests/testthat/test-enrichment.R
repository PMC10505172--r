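mk_table <- function(id, counts) count_table(id, counts)

test_that("log2E is the log-ratio of output to input frequency with floors", {
  input <- mk_table("input", c(a = 10, b = 40, c = 50, d = 0))
  out <- mk_table("CK1", c(a = 40, b = 40, c = 12, d = 8))
  e <- compute_log2E(input, out, mode = "selection")
  expect_equal(e$log2E[e$peptide_id == "a"], 2)          # 0.4 / 0.1
  expect_equal(e$log2E[e$peptide_id == "b"], 0)          # unchanged
  # peptide d absent from input: floor = lowest input proportion (0.1)
  expect_equal(e$log2E[e$peptide_id == "d"], log2(0.08 / 0.1))
  expect_true(all(is.finite(e$log2E)))

  # hand application of the printed substitution rule
  input2 <- mk_table("input", c(p = 999, q = 1, r = 0))
  out2 <- mk_table("CK1", c(p = 992, q = 0, r = 8))
  e2 <- compute_log2E(input2, out2, mode = "selection")
  expect_equal(e2$log2E[e2$peptide_id == "r"], 3)        # 0.008 / 0.001
  # selection mode omits the unrecovered peptide q
  expect_false("q" %in% e2$peptide_id)

  expect_error(compute_log2E(structure(data.frame(
    peptide_id = "a", count = 0, frequency = 0), class = c("count_table", "data.frame")),
    out, mode = "selection"), "zero")
})

test_that("mutagenesis mode floors missing output proportions", {
  input <- mk_table("input", c(a = 500, b = 250, c = 250))
  out <- mk_table("CK1", c(a = 990, b = 10, c = 0))
  e <- compute_log2E(input, out, mode = "mutagenesis")
  # c unseen in output: floored at the lowest output proportion (0.01)
  expect_equal(e$log2E[e$peptide_id == "c"], log2(0.01 / 0.25))
  expect_true(all(c("a", "b", "c") %in% e$peptide_id))
  expect_true(all(is.finite(e$log2E)))
})

test_that("log2E matches a brute-force oracle on random count fixtures", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    ids <- sprintf("p%02d", seq_len(n))
    cin <- setNames(rpois(n, 30) * rbinom(n, 1, 0.85), ids)
    cout <- setNames(rpois(n, 30) * rbinom(n, 1, 0.8), ids)
    if (sum(cin) == 0 || sum(cout) == 0) next
    e <- compute_log2E(mk_table("in", cin), mk_table("o", cout),
                      mode = "selection")
    fin <- cin / sum(cin); fout <- cout / sum(cout)
    floor_in <- min(fin[fin > 0])
    for (id in ids[cout > 0]) {
      fi <- if (fin[id] > 0) fin[id] else floor_in
      expect_equal(e$log2E[e$peptide_id == id], unname(log2(fout[id] / fi)))
    }
    expect_setequal(e$peptide_id, ids[cout > 0])
  }
})

test_that("increasing one output count never lowers that peptide's rank", {
  set.seed(77)
  cin <- setNames(rpois(10, 40) + 1, letters[1:10])
  cout <- setNames(rpois(10, 40) + 1, letters[1:10])
  input <- mk_table("in", cin)
  base <- compute_log2E(input, mk_table("o", cout), "selection")
  base_rank <- rank(base$log2E)[base$peptide_id == "e"]
  for (bump in c(5, 50, 500)) {
    cout2 <- cout; cout2["e"] <- cout["e"] + bump
    e2 <- compute_log2E(input, mk_table("o", cout2), "selection")
    expect_gte(rank(e2$log2E)[e2$peptide_id == "e"], base_rank)
  }
})

test_that("median CI reproduces binomial order-statistic ranks", {
  v <- 1:100
  ci <- median_ci(v)
  # ranks from the binomial CDF oracle, symmetric about 50/51
  expect_equal(unname(ci), unname(median_ci_oracle(v)))
  j <- which(v == ci[["lower"]])
  expect_equal(101 - j, which(v == ci[["upper"]]))
  expect_gte(1 - 2 * pbinom(j - 1, 100, 0.5), 0.95)

  expect_equal(unname(median_ci(rep(3.5, 20))), c(3.5, 3.5))
  set.seed(5)
  x <- rnorm(30)
  expect_equal(median_ci(x + 10), median_ci(x) + 10)
  expect_error(median_ci(rnorm(4)), "too small")

  set.seed(6)
  for (n in c(6, 11, 25, 60)) {
    x <- rcauchy(n)
    expect_equal(median_ci(x), median_ci_oracle(x))
  }
})

test_that("residue profiles sum enriched tile log2E and match the oracle", {
  parent <- list(id = "P", sequence = random_peptide(40))
  lib <- design_library(data.frame(id = "P", sequence = parent$sequence))
  reps <- lib$members

  # single enriched tile covering residues 1..16
  tab <- structure(data.frame(peptide_id = reps$peptide_id[reps$start == 1 &
                                reps$variant_class == "WT"],
                              chemokine_id = "CK1", log2E = 2),
                   class = c("enrichment_table", "data.frame"))
  pr <- residue_profile(tab, lib, parent)
  expect_equal(pr$rlog2E, c(rep(2, 16), rep(0, 24)))

  # negative entries contribute nothing
  tab$log2E <- -1
  pr2 <- residue_profile(tab, lib, parent)
  expect_equal(pr2$rlog2E, rep(0, 40))

  # absent smoothing at exactly the first and last 3 residues (k = 7)
  expect_equal(which(is.na(pr$smoothed)), c(1:3, 38:40))

  # oracle equivalence over random enrichment fixtures
  set.seed(41)
  for (i in 1:50) {
    k <- sample(3:12, 1)
    idx <- sample(nrow(reps), k)
    tabr <- structure(data.frame(peptide_id = reps$peptide_id[idx],
                                 chemokine_id = sample(c("CK1", "CK2"), k, TRUE),
                                 log2E = round(rnorm(k, 1, 2), 2)),
                      class = c("enrichment_table", "data.frame"))
    prr <- residue_profile(tabr, lib, parent)
    expect_equal(prr$rlog2E, rlog2E_oracle(tabr, reps, 40))
  }
})

test_that("rolling median matches the sorted-window oracle", {
  set.seed(51)
  for (i in 1:100) {
    v <- rnorm(sample(7:60, 1))
    expect_equal(as.numeric(zoo::rollmedian(v, k = 7, fill = NA)),
                 rollmedian_oracle(v, 7L))
  }
})

test_that("ROI detection returns maximal runs above the CI upper bound", {
  mk_profile <- function(v, upper) {
    structure(list(parent_id = "P", sequence = strrep("A", length(v)),
                   rlog2E = v, smoothed = v,
                   median_ci = c(lower = 0, upper = upper),
                   roi = NULL), class = "residue_profile")
  }
  flat <- mk_profile(rep(1, 30), upper = 2)
  expect_equal(nrow(detect_roi(flat)), 0L)

  two <- rep(0, 40); two[5:9] <- 10; two[20:26] <- 8
  roi <- detect_roi(mk_profile(two, upper = 2))
  expect_equal(roi$start, c(5L, 20L))
  expect_equal(roi$end, c(9L, 26L))

  # residues with absent smoothed values never qualify
  v <- rep(10, 20)
  p <- mk_profile(v, upper = 2)
  p$smoothed[1:3] <- NA
  expect_equal(detect_roi(p)$start, 4L)
})

test_that("promiscuity filter applies strict thresholds", {
  tab <- structure(data.frame(
    peptide_id = c(rep("hit", 3), rep("edge", 3), rep("few", 2)),
    chemokine_id = c("c1", "c2", "c3", "c1", "c2", "c3", "c1", "c2"),
    log2E = c(6, 7, 5.1, 6, 7, 5.0, 9, 9)),
    class = c("enrichment_table", "data.frame"))
  expect_equal(promiscuous_peptides(tab), "hit")
  expect_equal(promiscuous_peptides(tab, min_chemokines = 2), c("edge", "few", "hit"))
  empty <- tab[0, ]
  expect_equal(promiscuous_peptides(empty), character(0))
})

test_that("delta log2E subtracts the parental value per chemokine", {
  members <- data.frame(peptide_id = c("WT", "M1", "M2"),
                        mutation_label = c("", "T6E", "C13A"))
  tab <- structure(data.frame(
    peptide_id = rep(c("WT", "M1", "M2"), each = 2),
    chemokine_id = rep(c("c1", "c2"), 3),
    log2E = c(6, 5, 4, 5, 6, 2)),
    class = c("enrichment_table", "data.frame"))
  d <- delta_log2E(tab, "WT", members)
  expect_equal(d$delta_log2E[d$peptide_id == "M1" & d$chemokine_id == "c1"], -2)
  expect_equal(d$delta_log2E[d$peptide_id == "M1" & d$chemokine_id == "c2"], 0)
  expect_equal(d$delta_log2E[d$peptide_id == "WT"], c(0, 0))
  expect_equal(d$position[d$peptide_id == "M2"], c(13L, 13L))
  expect_equal(d$wt_res[d$peptide_id == "M2"][1], "C")
  expect_equal(d$mut_res[d$peptide_id == "M2"][1], "A")

  # chemokine without a parental entry is skipped with a warning
  tab3 <- rbind(tab, data.frame(peptide_id = "M1", chemokine_id = "c3",
                                log2E = 1))
  class(tab3) <- class(tab)
  expect_warning(d3 <- delta_log2E(tab3, "WT", members), "c3")
  expect_false("c3" %in% d3$chemokine_id)
})

test_that("total log2E aggregates over chemokines present", {
  tab <- structure(data.frame(peptide_id = c("a", "a", "b"),
                              chemokine_id = c("c1", "c2", "c1"),
                              log2E = c(1.5, 2.5, -1)),
                   class = c("enrichment_table", "data.frame"))
  tot <- total_log2E(tab)
  expect_equal(tot$total_log2E[tot$peptide_id == "a"], 4)
  expect_equal(tot$total_log2E[tot$peptide_id == "b"], -1)
})
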
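# Metabolome stage: exact-mass annotation, normalization, age
# correlation and differential statistics with the published filters.

test_that("exact-mass annotation matches both negative-mode adducts", {
  db <- data.frame(compound_id = "C1", mass = 180.0634)
  # deprotonated ion: 180.0634 - 1.007276 = 179.056124
  ann <- annotate_ions(c(ion1 = 179.0565), db, tolerance = 0.001)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$adduct, "M-H")
  expect_equal(ann$mass_error, 179.0565 - 179.056124, tolerance = 1e-9)
  # fluoride adduct: 180.0634 + 18.998403 = 199.061803
  ann2 <- annotate_ions(c(ion2 = 199.0618), db, tolerance = 0.001)
  expect_equal(ann2$adduct, "M+F")
  # adducts can be restricted
  expect_equal(nrow(annotate_ions(c(ion2 = 199.0618), db,
                                  adducts = "M-H")), 0L)
  # empty database annotates nothing but errors never
  empty <- annotate_ions(c(ion1 = 179.0565),
                         data.frame(compound_id = character(0),
                                    mass = numeric(0)))
  expect_equal(nrow(empty), 0L)
  expect_error(annotate_ions(c(ion1 = 179.0565), db, tolerance = 0),
               "positive")
})

test_that("shrinking the tolerance never adds annotation candidates", {
  set.seed(5)
  db <- data.frame(compound_id = sprintf("C%d", 1:40),
                   mass = runif(40, 80, 900))
  mz <- setNames(db$mass - 1.007276 + runif(40, -0.002, 0.002),
                 sprintf("I%d", 1:40))
  wide <- annotate_ions(mz, db, tolerance = 0.002)
  narrow <- annotate_ions(mz, db, tolerance = 0.0005)
  key <- function(a) paste(a$ion_id, a$compound_id, a$adduct)
  expect_true(all(key(narrow) %in% key(wide)))
  expect_lte(nrow(narrow), nrow(wide))
})

test_that("normalization removes per-sample loading on the raw scale", {
  set.seed(8)
  base <- matrix(2^runif(200, 8, 16), nrow = 50,
                 dimnames = list(sprintf("I%d", 1:50), sprintf("S%d", 1:4)))
  scaled <- sweep(base, 2, c(1, 2, 0.5, 1.5), "*")
  norm <- normalize_intensities(scaled, log2_transform = FALSE)
  sorted <- apply(norm, 2, sort)
  expect_lt(max(sorted - sorted[, 1]), 1e-9)
  expect_error(normalize_intensities(-base), "nonnegative")
})

test_that("age correlation recovers exact trends and excludes constants", {
  donors <- data.frame(sample_id = sprintf("S%d", 1:10),
                       age = c(21, 22, 23, 24, 25, 57, 59, 61, 63, 65),
                       group = factor(rep(c("young", "old"), each = 5),
                                      levels = c("young", "old")))
  mat <- rbind(
    age_ion = donors$age,
    const = rep(3, 10),
    noise = c(5, 4, 6, 5, 4, 6, 5, 4, 6, 5)
  )
  colnames(mat) <- donors$sample_id
  expect_warning(res <- correlate_with_age(mat, donors), "constant")
  expect_equal(res$rho_age[res$ion_id == "age_ion"], 1)
  expect_true(is.na(res$q_age[res$ion_id == "const"]))
  # q family excludes the undefined ion
  expect_equal(sum(!is.na(res$q_age)), 2L)
  bad <- donors
  bad$sample_id[1] <- "SX"
  expect_error(correlate_with_age(mat, bad), "SX")
})

test_that("correlation significance uses strict inequalities", {
  res <- data.frame(ion_id = c("a", "b", "c", "d"),
                    rho_age = c(0.3, 0.25, -0.4, -0.3),
                    p_age = rep(0.001, 4),
                    q_age = c(0.005, 0.005, 0.02, 0.005))
  sig <- significant_ions_correlation(res)
  expect_setequal(sig$ion_id, c("a", "d"))
  expect_equal(sig$direction[sig$ion_id == "a"], "positive")
  expect_equal(sig$direction[sig$ion_id == "d"], "negative")
})

test_that("differential analysis recovers a planted 1.8-fold group ratio", {
  set.seed(12)
  donors <- data.frame(sample_id = sprintf("S%d", 1:46),
                       age = c(sample(20:25, 23, TRUE), sample(55:66, 23, TRUE)),
                       group = factor(rep(c("young", "old"), each = 23),
                                      levels = c("young", "old")))
  n_ion <- 60
  mat <- matrix(rnorm(n_ion * 46, mean = 12, sd = 0.05), nrow = n_ion,
                dimnames = list(sprintf("I%d", 1:n_ion), donors$sample_id))
  mat["I1", donors$group == "old"] <- mat["I1", donors$group == "old"] +
    log2(1.8)
  res <- differential_metabolites(mat, donors)
  est <- res$log2fc[res$ion_id == "I1"]
  expect_equal(est, log2(1.8), tolerance = 0.05)
  expect_lt(res$q[res$ion_id == "I1"], 0.05)
  # q-values are monotone in p
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_error(differential_metabolites(mat[, 1:23], donors[1:23, ]),
               "group")
})

test_that("differential significance uses strict inequalities", {
  res <- data.frame(ion_id = c("a", "b", "c"),
                    log2fc = c(0.5, 0.1, -0.3),
                    t = 0, p = 0.001, q = c(0.01, 0.01, 0.2))
  sig <- significant_ions_differential(res)
  expect_equal(sig$ion_id, "a")
  expect_equal(sig$direction, "up")
})
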
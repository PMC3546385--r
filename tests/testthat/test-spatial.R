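test_that("male mean rut locations average harem records only", {
  cen <- tibble::tibble(
    rut_year = c(1L, 2L, 1L, 1L),
    date = as.Date("2000-10-10") + 0:3,
    individual_id = c("m1", "m1", "m2", "f1"),
    easting = c(1000, 1200, 500, 900),
    northing = c(2000, 2000, 700, 900),
    harem_holder = c(TRUE, TRUE, TRUE, FALSE)
  )
  loc <- male_rut_locations(cen)
  expect_identical(loc$mean_easting[loc$male_id == "m1"], 1100)
  expect_identical(loc$mean_northing[loc$male_id == "m1"], 2000)
  expect_identical(loc$n_records[loc$male_id == "m2"], 1L)
  expect_false("f1" %in% loc$male_id)
  # translation leaves pairwise distances unchanged
  cen2 <- dplyr::mutate(cen, easting = easting + 250, northing = northing - 40)
  loc2 <- male_rut_locations(cen2)
  d1 <- dist(loc[, c("mean_easting", "mean_northing")])
  d2 <- dist(loc2[, c("mean_easting", "mean_northing")])
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
})

test_that("pairwise table pairs every located male once", {
  ped <- aunt_halfniece_pedigree()
  K <- kinship_matrix(ped)
  loc <- tibble::tibble(
    male_id = c("S1", "S2", "D"),
    mean_easting = c(0, 300, 0),
    mean_northing = c(0, 0, 400),
    n_records = 1L
  )
  pt <- male_pairwise_table(K, loc)
  expect_identical(nrow(pt), 3L)
  row <- pt[(pt$male1 == "S1" & pt$male2 == "S2") |
              (pt$male1 == "S2" & pt$male2 == "S1"), ]
  expect_identical(row$relatedness, 0)       # founders unrelated
  expect_identical(row$distance, 300)
  # father and son at the same location
  K2 <- kinship_matrix(pedigree(tibble::tibble(
    id = c("pa", "ma", "son"), sex = c("M", "F", "M"),
    birth_year = c(1, 1, 2),
    mother_id = c(NA, NA, "ma"), father_id = c(NA, NA, "pa")
  )))
  loc2 <- tibble::tibble(male_id = c("pa", "son"),
                         mean_easting = 0, mean_northing = 0,
                         n_records = 1L)
  pt2 <- male_pairwise_table(K2, loc2)
  expect_identical(pt2$relatedness, 0.5)
  expect_identical(pt2$distance, 0)
})

test_that("constant relatedness gives a slope of exactly zero", {
  set.seed(8)
  n <- 10
  loc <- tibble::tibble(male_id = sprintf("m%02d", 1:n),
                        mean_easting = runif(n, 0, 2000),
                        mean_northing = runif(n, 0, 2000),
                        n_records = 1L)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- tibble::tibble(
    male1 = loc$male_id[idx[, 1]], male2 = loc$male_id[idx[, 2]],
    relatedness = 0.2,
    distance = sqrt((loc$mean_easting[idx[, 1]] - loc$mean_easting[idx[, 2]])^2 +
                      (loc$mean_northing[idx[, 1]] - loc$mean_northing[idx[, 2]])^2)
  )
  fit <- fit_relatedness_distance(pairs, n_permutations = 49, seed = 1)
  expect_equal(fit$slope, 0, tolerance = 1e-14)
})

test_that("slope estimate is invariant to rotation and translation", {
  st <- tiny_study()
  K <- kinship_matrix(st$individuals)
  loc <- male_rut_locations(st$census, st$individuals)
  fit1 <- fit_relatedness_distance(male_pairwise_table(K, loc),
                                   n_permutations = 9, seed = 2)
  th <- 0.7
  rot <- loc
  rot$mean_easting <- cos(th) * loc$mean_easting -
    sin(th) * loc$mean_northing + 5000
  rot$mean_northing <- sin(th) * loc$mean_easting +
    cos(th) * loc$mean_northing - 1000
  fit2 <- fit_relatedness_distance(male_pairwise_table(K, rot),
                                   n_permutations = 9, seed = 2)
  expect_equal(fit1$slope, fit2$slope, tolerance = 1e-9)
})

test_that("permutation p is reproducible and calibrated under the null", {
  ped <- random_pedigree(n = 28, n_founders = 8, seed = 5)
  K <- kinship_matrix(ped)
  males <- ped$id[ped$sex == "M"]
  reject <- logical(200)
  for (s in 1:200) {
    set.seed(4000 + s)
    loc <- tibble::tibble(male_id = males,
                          mean_easting = runif(length(males), 0, 3000),
                          mean_northing = runif(length(males), 0, 2000),
                          n_records = 1L)
    pairs <- male_pairwise_table(K, loc)
    fit <- fit_relatedness_distance(pairs, n_permutations = 199, seed = s)
    reject[s] <- fit$p_permutation < 0.05
  }
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.08)
  # reproducibility under a fixed seed
  set.seed(4001)
  loc <- tibble::tibble(male_id = males,
                        mean_easting = runif(length(males), 0, 3000),
                        mean_northing = runif(length(males), 0, 2000),
                        n_records = 1L)
  pairs <- male_pairwise_table(K, loc)
  f1 <- fit_relatedness_distance(pairs, n_permutations = 99, seed = 7)
  f2 <- fit_relatedness_distance(pairs, n_permutations = 99, seed = 7)
  expect_identical(f1$p_permutation, f2$p_permutation)
  expect_identical(f1$perm_slopes, f2$perm_slopes)
})

test_that("male philopatry produces a negative relatedness-distance slope", {
  cfg <- generator_config(n_years = 10L, n_founder_females = 40L,
                          n_founder_males = 16L, male_philopatry = 0.9)
  st <- generate_study(cfg, seed = 55)
  K <- kinship_matrix(st$individuals)
  loc <- male_rut_locations(st$census, st$individuals)
  fit <- fit_relatedness_distance(male_pairwise_table(K, loc),
                                  n_permutations = 199, seed = 3)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_permutation, 0.05)
})

test_that("degenerate spatial designs are rejected", {
  pairs <- tibble::tibble(male1 = c("a", "a", "b"),
                          male2 = c("b", "c", "c"),
                          relatedness = c(0.1, 0.2, 0.3),
                          distance = c(100, 100, 100))
  expect_error(fit_relatedness_distance(pairs), "distances are equal")
  expect_error(
    fit_relatedness_distance(tibble::tibble(
      male1 = "a", male2 = "b", relatedness = 0.1, distance = 5
    )),
    "three males"
  )
})
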
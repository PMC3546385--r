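test_that("pair opportunities follow receptivity and rut presence", {
  st <- micro_study()
  po <- pair_opportunities(st$ped, st$calvings, st$census)
  # DAM1 x MA mated 1995 and 1996
  row <- po[po$female_id == "DAM1" & po$male_id == "MA", ]
  expect_identical(row$mated_years[[1]], c(1995L, 1996L))
  expect_identical(row$n_mated, 2L)
  expect_identical(row$opportunity_years[[1]], c(1995L, 1996L))
  # DAM2 x MB mated 1995 only; DAM2 did not calve from rut 1996
  row2 <- po[po$female_id == "DAM2" & po$male_id == "MB", ]
  expect_identical(row2$opportunity_years[[1]], 1995L)
  expect_identical(row2$n_opportunity, 1L)
})

test_that("male absent from later censuses removes the opportunity", {
  st <- micro_study()
  cen <- st$census[!(st$census$individual_id == "MA" &
                       st$census$rut_year == 1996), ]
  ped2 <- tibble::as_tibble(st$ped)
  ped2$father_id[ped2$id == "K3"] <- "MB"   # so MA mates 1995 only
  po <- pair_opportunities(pedigree(ped2), st$calvings, cen)
  row <- po[po$female_id == "DAM1" & po$male_id == "MA", ]
  expect_identical(row$opportunity_years[[1]], 1995L)
  # with MA censused in 1996 the opportunity exists
  po2 <- pair_opportunities(pedigree(ped2), st$calvings, st$census)
  row2 <- po2[po2$female_id == "DAM1" & po2$male_id == "MA", ]
  expect_identical(row2$opportunity_years[[1]], c(1995L, 1996L))
})

test_that("a sire without a recorded dam is rejected", {
  bad <- tibble::tibble(
    id = c("M1", "K"), sex = c("M", "M"), birth_year = c(1, 2),
    mother_id = c(NA, NA), father_id = c(NA, "M1")
  )
  st <- micro_study()
  expect_error(pair_opportunities(pedigree(bad), st$calvings, st$census),
               "sire but no dam")
})

test_that("re-mating percentages use multi-opportunity denominators", {
  # 1456 pairs with multi-year opportunity, 134 of which re-mated
  po <- tibble::tibble(
    female_id = sprintf("f%04d", 1:1456),
    male_id = sprintf("m%04d", 1:1456),
    n_mated = c(rep(2L, 134), rep(1L, 1322)),
    n_opportunity = rep(2L, 1456)
  )
  rs <- remating_stats(po)
  expect_equal(rs$pct_pairs_remating, 100 * 134 / 1456, tolerance = 1e-12)
  expect_identical(round(rs$pct_pairs_remating, 1), 9.2)
  # no re-mating
  po$n_mated <- 1L
  expect_identical(remating_stats(po)$pct_pairs_remating, 0)
  # a single re-mated pair
  one <- tibble::tibble(female_id = "f", male_id = "m",
                        n_mated = 2L, n_opportunity = 2L)
  rs1 <- remating_stats(one)
  expect_identical(unlist(rs1, use.names = FALSE), c(100, 100, 100))
  # zero denominator reported missing
  none <- tibble::tibble(female_id = "f", male_id = "m",
                         n_mated = 1L, n_opportunity = 1L)
  expect_true(all(is.na(remating_stats(none))))
})

test_that("female mate diversity is distinct sires over calves", {
  ped <- pedigree(tibble::tibble(
    id = c("F1", "F2", "A", "B", "C", paste0("k", 1:7)),
    sex = c("F", "F", "M", "M", "M", rep("F", 7)),
    birth_year = c(1, 1, 1, 1, 1, 2:8),
    mother_id = c(NA, NA, NA, NA, NA, "F1", "F1", "F1", "F2", "F2", "F2", "F2"),
    father_id = c(NA, NA, NA, NA, NA, "A", "B", "C", "A", "A", "B", "B")
  ))
  # F1: 3 calves by 3 males (1.0); F2: 4 calves by 2 males (0.5)
  expect_equal(female_mate_diversity(ped), mean(c(1, 0.5)), tolerance = 1e-12)
})

test_that("intralineage ratio counts matrilines per male's mates", {
  ped <- pedigree(tibble::tibble(
    id = c("L1", "L2", "S", "d1", "d2", "d3", "d4",
           "M1", "M2", paste0("c", 1:5)),
    sex = c("F", "F", "M", "F", "F", "F", "F", "M", "M", rep("M", 5)),
    birth_year = c(1, 1, 1, 2, 2, 2, 2, 1, 1, 3, 3, 3, 3, 3),
    mother_id = c(NA, NA, NA, "L1", "L1", "L2", "L2", NA, NA,
                  "d1", "d2", "d3", "d4", "d1"),
    father_id = c(NA, NA, NA, "S", "S", "S", "S", NA, NA,
                  "M1", "M1", "M1", "M1", "M2")
  ))
  # M1 mated d1..d4 from 2 matrilines -> 0.5; M2 mated d1 only -> 1;
  # founder sire S mated L1 and L2, two matrilines -> 1
  expect_equal(intralineage_polygyny(ped), mean(c(0.5, 1, 1)),
               tolerance = 1e-12)
})

test_that("mean pairwise relatedness matches the oracle", {
  ped <- random_pedigree(n = 25, seed = 77)
  Ko <- oracle_kinship_matrix(ped)
  expected <- mean(2 * Ko[upper.tri(Ko)])
  expect_equal(mean_pairwise_relatedness(ped), expected, tolerance = 1e-12)
  # two unrelated founders; then one parent-offspring pair
  two <- pedigree(tibble::tibble(
    id = c("a", "b"), sex = c("F", "M"),
    mother_id = c(NA, NA), father_id = c(NA, NA)
  ))
  expect_identical(mean_pairwise_relatedness(two), 0)
  po <- pedigree(tibble::tibble(
    id = c("a", "k"), sex = c("F", "F"),
    birth_year = c(1, 2), mother_id = c(NA, "a"), father_id = c(NA, NA)
  ))
  expect_identical(mean_pairwise_relatedness(po), 0.5)
})

test_that("inbreeding summaries count nonzero and close events", {
  founders <- pedigree(tibble::tibble(
    id = letters[1:4], sex = c("F", "M", "F", "M"),
    mother_id = NA_character_, father_id = NA_character_
  ))
  expect_identical(
    unlist(inbreeding_stats(founders), use.names = FALSE), c(0, 0, 0)
  )
  # ten outbred calves plus one full-sib-mating calf
  ped <- tibble::tibble(
    id = c("m0", "f0", "s", "d", "x", paste0("o", 1:6)),
    sex = c("M", "F", "M", "F", "F", rep(c("F", "M"), 3)),
    birth_year = c(1, 1, 2, 2, 3, rep(3, 6)),
    mother_id = c(NA, NA, "f0", "f0", "d", rep("f0", 6)),
    father_id = c(NA, NA, "m0", "m0", "s", rep(NA, 6))
  )
  st <- inbreeding_stats(pedigree(ped))
  expect_identical(st$n_f_nonzero, 1L)
  expect_identical(st$n_f_close, 1L)
  expect_equal(st$mean_f, 0.25 / 11, tolerance = 1e-12)
  # the three-loop coefficient 0.08008 is nonzero but not a close event
  # (the focal calf's father also carries a small coefficient through
  # the shared great-great-grandmother, hence two nonzero entries)
  st6 <- inbreeding_stats(three_loop_pedigree())
  expect_identical(st6$n_f_nonzero, 2L)
  expect_identical(st6$n_f_close, 0L)
})

test_that("stat_block is deterministic and internally consistent", {
  st <- tiny_study()
  b1 <- stat_block(st$individuals, st$calvings, st$census)
  b2 <- stat_block(st$individuals, st$calvings, st$census)
  expect_identical(b1, b2)
  expect_identical(names(b1), STAT_NAMES)
  expect_true(all(!is.na(unlist(b1))))
  expect_true(b1$mean_full_sibship >= 1)
  expect_true(b1$mate_diversity > 0 && b1$mate_diversity <= 1)
  expect_true(b1$intralineage_ratio > 0 && b1$intralineage_ratio <= 1)
  expect_lte(b1$n_f_close, b1$n_f_nonzero)
  # the three percentages share one re-mated pair set and their stated
  # denominators
  po <- pair_opportunities(st$individuals, st$calvings, st$census)
  multi <- po[po$n_opportunity >= 2, ]
  rem <- po[po$n_mated >= 2, ]
  expect_equal(b1$pct_pairs_remating, 100 * nrow(rem) / nrow(multi),
               tolerance = 1e-12)
  expect_equal(b1$pct_females_remating,
               100 * dplyr::n_distinct(rem$female_id) /
                 dplyr::n_distinct(multi$female_id),
               tolerance = 1e-12)
  expect_equal(b1$pct_males_remating,
               100 * dplyr::n_distinct(rem$male_id) /
                 dplyr::n_distinct(multi$male_id),
               tolerance = 1e-12)
})
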
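test_that("relative contents are proportions of the sample total", {
  pt <- toy_peak_table()
  ct <- relative_content(pt)
  expect_equal(unname(ct[1, ]), c(20, 30, 50))
  expect_equal(unname(ct[4, ]), c(50, 0, 50))
  expect_equal(unname(rowSums(ct)), rep(100, 4), tolerance = 1e-9)

  one <- peak_table(matrix(7.3, 1, 1, dimnames = list(NULL, "solo")),
                    groups = "g")
  expect_equal(unname(relative_content(one)[1, 1]), 100)
})

test_that("a sample with zero total area is rejected by name", {
  areas <- rbind(c(1, 2), c(0, 0))
  colnames(areas) <- c("a", "b")
  expect_error(peak_table(areas, c("g1", "g2"), c("s1", "s2")), "s2")
  expect_error(peak_table(matrix(c(1, -1), 1, 2,
                                 dimnames = list(NULL, c("a", "b"))), "g"),
               "finite")
})

test_that("group aggregation gives mean and sample SD, permutation-invariant", {
  ct <- rbind(c(10, 90), c(10, 90), c(10, 90), c(10, 90),
              c(20, 80), c(30, 70), c(40, 60), c(10, 90))
  colnames(ct) <- c("a", "b")
  g <- rep(c("g1", "g2"), each = 4)
  prof <- group_profile(ct, g)
  expect_equal(prof$g1$mean_content, c(10, 90))
  expect_equal(prof$g1$sd_content, c(0, 0))
  expect_equal(prof$g2$mean_content, c(25, 75))
  expect_equal(prof$g2$sd_content, rep(stats::sd(c(20, 30, 40, 10)), 2))
  expect_equal(sum(prof$g2$mean_content), 100, tolerance = 1e-9)

  perm <- sample(nrow(ct))
  prof2 <- group_profile(ct[perm, , drop = FALSE], g[perm])
  expect_equal(prof2$g1$mean_content, prof$g1$mean_content)
  expect_equal(prof2$g2$sd_content, prof$g2$sd_content)
})

test_that("a single replicate aggregates to its own value with SD 0 and a warning", {
  ct <- matrix(c(40, 60), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(prof <- group_profile(ct, "g1"), "single replicate")
  expect_equal(prof$g1$mean_content, c(40, 60))
  expect_equal(prof$g1$sd_content, c(0, 0))
})

test_that("venn counts obey inclusion-exclusion on the packaged study and toys", {
  p <- rosa_group_profiles()
  v <- venn_counts(p$RR, p$RS)
  expect_equal(unname(v), c(48, 26, 13, 61))
  expect_equal(v[["n_union"]], v[["n1"]] + v[["n2"]] - v[["n_common"]])

  a <- toy_profile(c("x", "y", "z"), c(10, 20, 70))
  expect_equal(unname(venn_counts(a, a)), c(3, 3, 3, 3))
  b <- toy_profile(c("x", "y", "z", "q", "r", "s", "t"),
                   c(0, 0, 0, 10, 20, 30, 40))
  a2 <- toy_profile(c("x", "y", "z", "q", "r", "s", "t"),
                    c(30, 30, 40, 0, 0, 0, 0))
  expect_equal(unname(venn_counts(a2, b)), c(3, 4, 0, 7))
})

test_that("class composition conserves the profile total and matches the study", {
  p <- rosa_group_profiles()
  meta <- rosa_compound_metadata()
  cc <- class_composition(p$RS, meta)
  expect_equal(cc$total_content[cc$chem_class == "aldehyde"], 51.40)
  expect_equal(cc$total_content[cc$chem_class == "terpenoid"], 21.43,
               tolerance = 1e-9)
  expect_equal(sum(cc$total_content), sum(p$RS$mean_content))
})

test_that("presence patterns follow the four-quadrant rule", {
  p1 <- toy_profile(c("a", "b", "c", "d"), c(16.16, 0.3, 0, 7.21),
                    group = "g1")
  p2 <- toy_profile(c("a", "b", "c", "d"), c(0, 0.2, 5, 7.83),
                    group = "g2")
  pat <- presence_pattern(p1, p2, high_threshold = 3)
  expect_equal(pat$pattern[match(c("a", "b", "c", "d"), pat$compound)],
               c("I", "II", "III", "IV"))
  expect_error(presence_pattern(p1, p2, high_threshold = 0))
})

test_that("wide and long CSV layouts load to the same peak table", {
  pt <- toy_peak_table()
  wide <- cbind(data.frame(sample_id = pt$samples$sample_id,
                           group = pt$samples$group), pt$areas)
  fw <- tempfile(fileext = ".csv")
  utils::write.csv(wide, fw, row.names = FALSE)
  long <- do.call(rbind, lapply(seq_len(nrow(pt$areas)), function(i)
    data.frame(sample_id = pt$samples$sample_id[i],
               group = pt$samples$group[i],
               compound = colnames(pt$areas),
               area = pt$areas[i, ])))
  fl <- tempfile(fileext = ".csv")
  utils::write.csv(long, fl, row.names = FALSE)

  pw <- read_peak_table(fw)
  pl <- read_peak_table(fl)
  expect_equal(pw$areas, pt$areas)
  expect_equal(pl$areas[, colnames(pt$areas)], pt$areas)
  expect_equal(pw$samples, pt$samples)
})

test_that("compound names are canonicalized and duplicates rejected", {
  expect_equal(canonical_name("  (E)-2-Hexenal  "), "(e)-2-hexenal")
  areas <- matrix(1:4, 2, 2, dimnames = list(NULL, c("A ", "a")))
  expect_error(peak_table(areas, c("g", "g")), "duplicate")
})
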
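# Evidence model and 2015 combining rules.

test_that("default strengths follow the code prefix and unknown codes are rejected", {
  expect_equal(default_strength("PP3"), "SUPPORTING")
  expect_equal(default_strength("BA1"), "STAND_ALONE")
  expect_equal(default_strength("PS4"), "STRONG")
  expect_equal(default_strength(c("PVS1", "PM6", "BS3", "BP7")),
               c("VERY_STRONG", "MODERATE", "STRONG", "SUPPORTING"))
  expect_error(default_strength("PX9"), "PX9")
  expect_error(parse_evidence("PM2,FOO1"), "FOO1")
})

test_that("evidence profiles parse, serialize and round-trip", {
  p <- parse_evidence("PM2,PP3_Strong,BS1")
  expect_s3_class(p, "evidence_profile")
  expect_equal(unname(p[c("PM2", "PP3", "BS1")]),
               c("MODERATE", "STRONG", "STRONG"))
  expect_equal(format_evidence(p), "PM2,PP3_Strong,BS1")
  # suffix parsing is case-insensitive and tolerates separators
  expect_equal(parse_evidence("BP4_VERY_STRONG"), parse_evidence("BP4_VeryStrong"))
  expect_equal(unname(parse_evidence("PP3_verystrong")["PP3"]), "VERY_STRONG")
  expect_equal(parse_evidence(format_evidence(p)), p)
  expect_length(parse_evidence(""), 0)
  expect_equal(combine_evidence(parse_evidence("")), "VUS")
})

test_that("duplicate codes replace the previous strength and BA1 owns STAND_ALONE", {
  p <- parse_evidence("PP3,PP3_Strong")
  expect_length(p, 1)
  expect_equal(unname(p["PP3"]), "STRONG")
  expect_error(evidence_profile("BS1", "STAND_ALONE"), "BS1")
  expect_error(evidence_profile("PVS1", "STAND_ALONE"), "PVS1")
  expect_silent(evidence_profile("BA1"))
})

test_that("combining rules match the published table on worked profiles", {
  cases <- list(
    list("", "VUS"),
    list("PVS1,PS1", "P"),
    list("PM1,PP3_Strong", "LP"),
    list("BS1,BP4_Strong", "B"),
    list("PM2,PP3", "VUS"),
    list("PS1,BS1", "VUS"),           # conflicting strong evidence
    list("PVS1", "VUS"),              # very strong alone is unclassified
    list("BA1,PVS1,PS1", "B"),        # stand-alone overrides
    list("PM1,PM2,PM3", "LP"),
    list("PVS1,PM2", "LP"),
    list("PS1,PM1,PM2,PM3", "P"),
    list("BS1,BP1", "LB"),
    list("BP1,BP4", "LB"),
    list("BS1", "LB")                 # single strong benign, extension rule
  )
  for (cs in cases) {
    expect_equal(combine_evidence(parse_evidence(cs[[1]])), cs[[2]],
                 label = paste("profile", cs[[1]]))
  }
  # engine options change the contested behaviours
  strict <- acmg_options(single_bs_is_lb = FALSE)
  expect_equal(combine_evidence(parse_evidence("BS1"), strict), "VUS")
  no_override <- acmg_options(ba1_overrides = FALSE)
  expect_equal(combine_evidence(parse_evidence("BA1,PVS1,PS1"), no_override), "VUS")
  expect_equal(combine_evidence(parse_evidence("BA1"), no_override), "B")
})

test_that("engine agrees with the transcribed rule table over all small profiles", {
  grid <- strength_count_grid(3)
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      prof <- profile_from_counts(grid[i, ], grid[j, ])
      expect_equal(
        combine_evidence(prof),
        oracle_classify(names(prof), unname(unclass(prof))),
        label = paste("profile", format_evidence(prof))
      )
    }
  }
})

test_that("classification is monotone in criterion strength and in added criteria", {
  set.seed(42)
  tiers <- classification_tiers()
  raise <- c(SUPPORTING = "MODERATE", MODERATE = "STRONG",
             STRONG = "VERY_STRONG")
  for (rep in 1:200) {
    grid_p <- strength_count_grid(3)
    cp <- grid_p[sample.int(nrow(grid_p), 1), ]
    cb <- grid_p[sample.int(nrow(grid_p), 1), ]
    prof <- profile_from_counts(cp, cb)
    base <- match(combine_evidence(prof), tiers)
    codes <- names(prof)
    strengths <- unname(unclass(prof))
    for (k in seq_along(codes)) {
      if (!strengths[k] %in% names(raise)) next
      s2 <- strengths; s2[k] <- raise[[strengths[k]]]
      if (s2[k] == "VERY_STRONG" && startsWith(codes[k], "B")) next
      new <- match(combine_evidence(evidence_profile(codes, s2)), tiers)
      if (startsWith(codes[k], "P")) {
        expect_gte(new, base)
      } else {
        expect_lte(new, base)
      }
    }
    # adding a pathogenic supporting item never moves toward the benign end
    unused_p <- setdiff(paste0("PP", 1:5), codes)
    if (length(unused_p)) {
      new <- match(combine_evidence(
        evidence_profile(c(codes, unused_p[1]), c(strengths, "SUPPORTING"))), tiers)
      expect_gte(new, base)
    }
    unused_b <- setdiff(paste0("BP", 1:7), codes)
    if (length(unused_b)) {
      new <- match(combine_evidence(
        evidence_profile(c(codes, unused_b[1]), c(strengths, "SUPPORTING"))), tiers)
      expect_lte(new, base)
    }
  }
})

test_that("combine is invariant to item order", {
  set.seed(7)
  for (rep in 1:50) {
    codes <- sample(acmg_codes(), sample(2:6, 1))
    codes <- codes[!duplicated(codes)]
    prof <- evidence_profile(codes)
    perm <- sample(seq_along(codes))
    expect_equal(combine_evidence(prof),
                 combine_evidence(evidence_profile(codes[perm])))
  }
})

test_that("enumerate_rule_table enumerates deterministic multisets", {
  t0 <- enumerate_rule_table(0)
  expect_equal(nrow(t0), 1)
  expect_equal(t0$classification, "VUS")
  t1p <- enumerate_rule_table(1, polarity = "pathogenic")
  expect_true(all(t1p$benign == "-"))
  expect_equal(t1p$classification[t1p$pathogenic == "1xVERY_STRONG"], "VUS")
  # sizes 0-2 over 4 strengths: 1 + 4 + (4 pairs + C(4,2)) = 15 multisets
  t2p <- enumerate_rule_table(2, polarity = "pathogenic")
  expect_equal(nrow(t2p), 15)
  t2 <- enumerate_rule_table(2)
  expect_equal(nrow(t2), 225)
  expect_identical(t2, enumerate_rule_table(2))
})
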
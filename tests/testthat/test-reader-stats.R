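test_that("sensitivity/specificity with exact CIs reproduce the reference tables", {
  # per-patient MVO detection, automated reader: 15/4/8/125 of 152
  ai_mvo <- contingency_2x2(tp = 15, fp = 4, fn = 8, tn = 125)
  ss <- sens_spec(ai_mvo)
  expect_equal(ss$display_pct, c(65, 97))
  expect_equal(ss$display_lo, c(42.7, 92.3))
  expect_equal(ss$display_hi, c(83.6, 99.1))
  # human MVO detection: 21/1/2/128
  hs <- sens_spec(contingency_2x2(21, 1, 2, 128))
  expect_equal(hs$display_pct, c(91, 99))
  expect_equal(hs$display_lo, c(72.0, 95.8))
  expect_equal(hs$display_hi, c(98.9, 100))
  # scar detection with no reference-negative cases: specificity undefined
  scar <- contingency_2x2(150, 0, 2, 0)
  st <- sens_spec(scar)
  expect_equal(st$display_pct[1], 99)
  expect_true(is.na(st$estimate_pct[2]))
  expect_error(specificity(scar), "undefined")
  expect_error(sensitivity(contingency_2x2(0, 3, 0, 5)), "undefined")
  expect_error(contingency_2x2(0, 0, 0, 0), "total")
})

test_that("Clopper-Pearson bounds match the Beta quantiles and closed forms", {
  # x = n: lower bound has the closed form 100 * (alpha/2)^(1/n)
  ci <- clopper_pearson(152, 152)
  expect_equal(ci$lo_pct, 100 * 0.025^(1 / 152))
  expect_equal(round(ci$lo_pct, 1), 97.6)
  expect_equal(ci$hi_pct, 100)
  expect_equal(round(clopper_pearson(15, 23)$lo_pct, 1), 42.7)
  expect_equal(clopper_pearson(0, 10)$lo_pct, 0)
  expect_error(clopper_pearson(5, 3), "x <= n")
  # ordering and monotonicity in x
  prev_lo <- -1
  for (x in 0:10) {
    ci <- clopper_pearson(x, 10)
    expect_lte(ci$lo_pct, ci$estimate_pct)
    expect_gte(ci$hi_pct, ci$estimate_pct)
    expect_gt(ci$lo_pct, prev_lo - 1e-12)
    prev_lo <- ci$lo_pct
  }
})

test_that("Cohen's kappa matches hand evaluation and a brute-force oracle", {
  expect_equal(cohen_kappa(diag(c(5, 7, 9)))$kappa, 1)
  # p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  m <- matrix(c(20, 10, 5, 15), 2, 2)
  expect_equal(cohen_kappa(m)$kappa, 0.4)
  # unweighted equals linear for k = 2
  expect_equal(cohen_kappa(m, "linear")$kappa, cohen_kappa(m, "none")$kappa)
  expect_error(cohen_kappa(matrix(c(3, 0, 0, 0), 2, 2)), "undefined")
  # from-scratch oracle on random small matrices
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    mm <- matrix(rpois(k * k, 5) + 1, k, k)
    n <- sum(mm)
    po <- 0; pe <- 0; pow <- 0; pew <- 0
    for (a in 1:k) for (b in 1:k) {
      w <- 1 - abs(a - b) / (k - 1)
      pij <- mm[a, b] / n
      pi_ <- sum(mm[a, ]) / n; p_j <- sum(mm[, b]) / n
      if (a == b) { po <- po + pij; pe <- pe + pi_ * p_j }
      pow <- pow + w * pij; pew <- pew + w * pi_ * p_j
    }
    expect_equal(cohen_kappa(mm)$kappa, (po - pe) / (1 - pe))
    expect_equal(cohen_kappa(mm, "linear")$kappa, (pow - pew) / (1 - pew))
  }
  td <- tidy(cohen_kappa(m))
  expect_equal(td$kappa, 0.4)
})

test_that("one-way chi-square matches the formula and stats::chisq.test", {
  z <- preference_chisq(50, 50)
  expect_equal(z$chi2, 0)
  expect_equal(z$p_value, 1)
  expect_equal(preference_chisq(30, 10)$chi2, 10)
  expect_equal(preference_chisq(30, 10)$chi2, preference_chisq(10, 30)$chi2)
  ref <- suppressWarnings(stats::chisq.test(c(30, 10)))
  expect_equal(preference_chisq(30, 10)$chi2, unname(ref$statistic))
  expect_equal(preference_chisq(30, 10)$p_value, ref$p.value)
  expect_error(preference_chisq(0, 0), "> 0")
})

test_that("rating tabulation gives multinomial-bootstrap CIs", {
  rec <- tibble::tibble(method = "AI", rating = rep("optimal", 12))
  tab <- tabulate_ratings(rec, B = 500)
  opt <- tab[tab$rating == "optimal", ]
  expect_equal(opt$pct, 100)
  expect_equal(c(opt$lo_pct, opt$hi_pct), c(100, 100))  # degenerate CI
  # proportions sum to 100 per method
  set.seed(2)
  rec2 <- tibble::tibble(
    method = rep(c("AI", "human"), each = 60),
    rating = sample(rating_levels(), 120, replace = TRUE))
  tab2 <- tabulate_ratings(rec2, B = 500)
  sums <- tapply(tab2$pct, tab2$method, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(tabulate_ratings(rec2[0, ]), "no rating")
  expect_error(tabulate_ratings(tibble::tibble(method = "AI", rating = "meh")),
               "unknown rating")
})

test_that("bootstrap CI width matches the normal approximation at p = 0.5", {
  rec <- tibble::tibble(method = "AI",
                        rating = rep(c("optimal", "too_big"), each = 50))
  tab <- tabulate_ratings(rec, B = 10000, seed = 42)
  opt <- tab[tab$rating == "optimal", ]
  half <- (opt$hi_pct - opt$lo_pct) / 2 / 100
  expect_lt(abs(half - 1.96 * sqrt(0.25 / 100)), 0.02)
  expect_lte(opt$lo_pct, opt$pct)
  expect_gte(opt$hi_pct, opt$pct)
})

test_that("bootstrap CIs cover the point estimate across seeds", {
  set.seed(5)
  rec <- tibble::tibble(method = "AI",
                        rating = sample(rating_levels(), 80, replace = TRUE))
  cover <- 0
  for (s in 1:30) {
    tab <- tabulate_ratings(rec, B = 400, seed = s)
    cover <- cover + all(tab$lo_pct <= tab$pct + 1e-9 &
                           tab$hi_pct >= tab$pct - 1e-9)
  }
  expect_gte(cover / 30, 0.99)
})

test_that("slice classification matches a brute-force tally on phantoms", {
  expect_equal(classify_slice(FALSE, FALSE), "TN")
  expect_equal(classify_slice(TRUE, FALSE), "FP")
  expect_equal(classify_slice(FALSE, TRUE), "FN")
  expect_equal(classify_slice(TRUE, TRUE), "TP")
  ca <- generate_case(small_params(scar_probability = 1), 6)
  # corrupt a copy: drop scar on its first scar slice, add scar on a clean one
  pred <- ca$labels
  s_on <- ca$meta$scar_slices[1]
  pred$labels[s_on, , ][pred$labels[s_on, , ] == 3L] <- 2L
  s_off <- setdiff(seq_len(dim(pred$labels)[1]), ca$meta$scar_slices)
  if (length(s_off)) pred$labels[s_off[1], 32, 32] <- 3L
  got <- classify_slices(pred, ca$labels, "scar")
  # exhaustive per-slice loop oracle
  for (s in seq_len(dim(pred$labels)[1])) {
    pp <- any(pred$labels[s, , ] == 3L); gg <- any(ca$labels$labels[s, , ] == 3L)
    want <- if (pp && gg) "TP" else if (!pp && !gg) "TN" else if (pp) "FP" else "FN"
    expect_equal(got$classification[s], want)
  }
  t2 <- presence_table(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(t2[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
})
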
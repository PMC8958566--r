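mk_multi <- function(n_subjects = 6, n_conditions = 8, n_params = 4, seed = 71) {
  set.seed(seed)
  tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                     condition = paste0("c", seq_len(n_conditions)),
                     parameter = paste0("p", seq_len(n_params))) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
}

test_that("within-subject z-scores have mean 0 and SD 1 per subject and parameter", {
  z <- zscore_within_subject(mk_multi())
  stats <- z |>
    dplyr::group_by(subject_id, parameter) |>
    dplyr::summarise(mu = mean(value), s = sd(value), .groups = "drop")
  expect_equal(stats$mu, rep(0, nrow(stats)), tolerance = 1e-12)
  expect_equal(stats$s, rep(1, nrow(stats)), tolerance = 1e-12)
})

test_that("z-scoring is location-invariant and rejects degenerate subjects", {
  tbl <- mk_multi()
  shifted <- tbl
  sel <- shifted$subject_id == "s01" & shifted$parameter == "p1"
  shifted$value[sel] <- shifted$value[sel] + 42
  expect_equal(zscore_within_subject(shifted)$value,
               zscore_within_subject(tbl)$value, tolerance = 1e-12)

  single <- tbl[tbl$condition == "c1", ]
  expect_error(zscore_within_subject(single), "< 2 conditions")

  flat <- tbl
  flat$value[flat$subject_id == "s02" & flat$parameter == "p3"] <- 7
  err <- expect_error(zscore_within_subject(flat), "zero within-subject")
  expect_match(conditionMessage(err), "s02")
  expect_match(conditionMessage(err), "p3")
})

test_that("similar-case imputation fills from same-condition donors and flags cells", {
  tbl <- mk_multi()
  drop_rows <- tbl$subject_id == "s01" & tbl$condition == "c3"
  reduced <- tbl[!drop_rows, ]
  imp <- impute_similar_case(reduced)
  expect_equal(nrow(imp), nrow(tbl))
  expect_equal(sum(imp$imputed), 4)  # 4 parameters of the dropped trial
  for (p in paste0("p", 1:4)) {
    donor_mean <- mean(tbl$value[tbl$condition == "c3" & tbl$parameter == p &
                                   tbl$subject_id != "s01"])
    got <- imp$value[imp$subject_id == "s01" & imp$condition == "c3" &
                       imp$parameter == p]
    expect_equal(got, donor_mean, tolerance = 1e-12)
  }

  constant <- tbl
  constant$value[constant$condition == "c5" & constant$parameter == "p2"] <- 0.7
  reduced2 <- constant[!(constant$subject_id == "s04" &
                           constant$condition == "c5" &
                           constant$parameter == "p2"), ]
  imp2 <- impute_similar_case(reduced2)
  expect_equal(imp2$value[imp2$subject_id == "s04" & imp2$condition == "c5" &
                            imp2$parameter == "p2"], 0.7)

  orphan <- tbl[!(tbl$condition == "c7" & tbl$parameter == "p1"), ]
  # reinsert a single missing cell with no donors anywhere
  orphan <- dplyr::bind_rows(orphan,
                             tibble::tibble(subject_id = "s01", condition = "c7",
                                            parameter = "p1", value = NA_real_))
  expect_error(impute_similar_case(orphan), "no donor")
})

test_that("component retention: Kaiser count and scree data", {
  sel <- select_n_components(c(3.2, 1.4, 0.9, 0.3, 0.2))
  expect_equal(sel$kaiser_k, 2)
  expect_equal(sel$scree$var_fraction, c(3.2, 1.4, 0.9, 0.3, 0.2) / 6)

  expect_equal(select_n_components(rep(1, 5))$kaiser_k, 0)  # strict inequality
  expect_error(select_n_components(c(1, 2)), "descending")
  expect_error(select_n_components(numeric(0)), "empty")
})

test_that("loading bands match their magnitude definitions", {
  expect_equal(classify_loading(c(0.65, -0.85, 0.10, 0.40, -0.55)),
               c("strong", "very strong", "below threshold",
                 "moderately low", "moderate"))
  expect_error(classify_loading(1.2), "<= 1")
})

test_that("k = 1 rotation is the identity up to sign; invariants hold for k = 2", {
  sf <- simulate_features(fast_config(n_subjects = 12, seed = 72))
  multi <- build_multivariate_table(sf$face, sf$vocal)
  multi <- impute_similar_case(zscore_within_subject(multi))

  p1 <- pca_varimax(multi, k = 1)
  expect_equal(abs(p1$rotmat), matrix(1), tolerance = 1e-12)
  expect_equal(abs(unname(p1$loadings[, 1])), abs(unname(p1$unrotated[, 1])),
               tolerance = 1e-12)

  p2 <- pca_varimax(multi, k = 2)
  # rotated loadings are an orthogonal mix of the unrotated ones
  expect_equal(unname(p2$unrotated %*% p2$rotmat), unname(p2$loadings),
               tolerance = 1e-9)
  expect_equal(unname(crossprod(p2$rotmat)), diag(2), tolerance = 1e-9)
  # communalities preserved by rotation
  expect_equal(rowSums(p2$loadings^2), rowSums(p2$unrotated^2),
               tolerance = 1e-9)
  # eigenvalue fractions sum to one
  expect_equal(sum(p2$eigenvalues) / length(p2$parameters), 1, tolerance = 1e-9)
  # total explained variance preserved by rotation
  expect_equal(sum(p2$var_explained),
               sum(p2$eigenvalues[1:2]) / length(p2$parameters),
               tolerance = 1e-9)
  # rotation does not decrease the varimax criterion
  expect_gte(varimax_criterion(p2$loadings) + 1e-12,
             varimax_criterion(p2$unrotated))
  # sign convention: dominant loading of each component is positive
  for (j in 1:2) expect_gt(max(p2$loadings[, j]), abs(min(p2$loadings[, j])) - 1e-12)

  expect_error(pca_varimax(multi, k = 99), "between 1 and")
})

test_that("the k = 2 rotation matches the brute-force varimax angle oracle", {
  sf <- simulate_features(fast_config(n_subjects = 16, seed = 73))
  multi <- build_multivariate_table(sf$face, sf$vocal)
  multi <- impute_similar_case(zscore_within_subject(multi))
  p2 <- pca_varimax(multi, k = 2)

  oracle_angle <- varimax_angle_oracle(p2$unrotated, step = 0.001)
  got_angle <- fold_angle(p2$rotmat)
  delta <- abs(got_angle - oracle_angle)
  delta <- min(delta, pi / 2 - delta)  # wrap at the quarter turn
  expect_lt(delta, 0.01)
})

test_that("rotated components separate the intensity and quality blocks", {
  sf <- simulate_features(sim_config(seed = 74))
  multi <- build_multivariate_table(sf$face, sf$vocal)
  multi <- impute_similar_case(zscore_within_subject(multi))
  p2 <- pca_varimax(multi, k = 2)

  L <- p2$loadings
  intensity_rc <- unname(which.max(abs(L["jaw", ])))
  quality_rc <- 3 - intensity_rc
  for (par in c("jaw", "pitch", "loudness")) {
    expect_equal(unname(which.max(abs(L[par, ]))), intensity_rc,
                 info = paste("intensity block:", par))
  }
  for (par in c("brow", "eyebrow", "lips", "duration", "timbre_brightness")) {
    expect_equal(unname(which.max(abs(L[par, ]))), quality_rc,
                 info = paste("quality block:", par))
  }
  # face and voice load with the designed signs
  expect_gt(L["pitch", intensity_rc] * L["jaw", intensity_rc], 0)
  expect_lt(L["duration", quality_rc] * L["brow", quality_rc], 0)

  # condition mean scores order along the designed dimensions
  cs <- p2$condition_scores
  rc_i <- paste0("RC", intensity_rc)
  rc_q <- paste0("RC", quality_rc)
  sc <- default_character_scheme()
  cs_char <- dplyr::inner_join(cs, sc, by = c(condition = "name"))
  mean_by <- function(d, col, by) {
    tapply(d[[col]], factor(d[[by]], c("low", "medium", "high")), mean)
  }
  assert_means <- mean_by(cs_char, rc_i, "assertiveness")
  expect_true(all(diff(assert_means) > 0))
  coop_sign <- sign(L["brow", rc_q])
  coop_means <- coop_sign * mean_by(cs_char, rc_q, "cooperativeness")
  expect_true(all(diff(coop_means) > 0))

  eg <- emotion_grid(emotion_names(FALSE))
  cs_emo <- dplyr::inner_join(cs, eg, by = c(condition = "name"))
  expect_gt(mean(cs_emo[[rc_i]][cs_emo$arousal == "high"]),
            mean(cs_emo[[rc_i]][cs_emo$arousal == "low"]))
  expect_gt(coop_sign * mean(cs_emo[[rc_q]][cs_emo$valence == "positive"]),
            coop_sign * mean(cs_emo[[rc_q]][cs_emo$valence == "negative"]))
})
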
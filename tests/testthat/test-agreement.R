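# Cohen's kappa and the agreement-table conventions.

test_that("kappa handles identity, chance and disagreement patterns", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0))$value, 1)
  # one rater constant -> kappa 0
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 1, 1, 1))$value, 0)
  # both constant, identical -> undefined
  expect_identical(cohens_kappa(rep(1, 6), rep(1, 6))$status, "na")
  # both constant, different categories -> pe = 0, kappa 0 (documented choice)
  k <- cohens_kappa(rep(1, 4), rep(0, 4))
  expect_identical(k$status, "ok")
  expect_equal(k$value, 0)
  # empty stratum -> dash
  expect_identical(cohens_kappa(integer(0), integer(0))$status, "dash")
  expect_identical(format_kappa(cohens_kappa(integer(0), integer(0))), "-")
  expect_error(cohens_kappa(c(1, 0), c(1, 0, 1)),
               class = "fundusXAI_input_error")
})

test_that("kappa is symmetric and bounded below by -1", {
  set.seed(111)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    ka <- cohens_kappa(a, b); kb <- cohens_kappa(b, a)
    expect_identical(ka$status, kb$status)
    if (ka$status == "ok") {
      expect_equal(ka$value, kb$value)
      expect_gte(ka$value, -1)
      expect_lte(ka$value, 1)
    }
  }
})

test_that("kappa equals the contingency oracle on every joint table n <= 8", {
  for (n in 1:8) {
    for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b)) {
      d <- n - a - b - c_
      v <- vectors_from_2x2(a, b, c_, d)
      got <- cohens_kappa(v$A, v$B)
      want <- kappa_oracle_2x2(a, b, c_, d)
      if (is.na(want)) {
        expect_identical(got$status, "na")
      } else {
        expect_equal(got$value, want)
        # exactly one rater constant -> po == pe -> kappa 0
        constA <- (a + b) %in% c(0L, n); constB <- (a + c_) %in% c(0L, n)
        if (xor(constA, constB)) expect_equal(got$value, 0)
      }
    }
  }
})

test_that("kappa is 1 only for identical non-constant vectors", {
  set.seed(131)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    k <- cohens_kappa(a, b)
    if (k$status == "ok" && isTRUE(all.equal(k$value, 1))) {
      expect_identical(a, b)
      expect_gt(var(a), 0)
    }
  }
})

test_that("rater vectors validate image alignment", {
  ra <- rater_vector(c("a", "b"), c(1, 0))
  rb <- rater_vector(c("a", "b"), c(1, 1))
  expect_equal(cohens_kappa(ra, rb)$value, 0)
  rc <- rater_vector(c("b", "a"), c(1, 0))
  expect_error(cohens_kappa(ra, rc), class = "fundusXAI_input_error")
  expect_error(rater_vector("a", c(1, 0)), class = "fundusXAI_input_error")
})

test_that("agreement table equals brute-force contingency recomputation", {
  set.seed(123)
  n_img <- 40
  ids <- sprintf("im%02d", 1:n_img)
  grade <- sample(0:4, n_img, replace = TRUE)
  correct <- sample(c(TRUE, FALSE), n_img, replace = TRUE)
  lesions <- c("MA", "EX", "HE")
  records <- do.call(rbind, lapply(lesions, function(lt) {
    data.frame(image_id = ids, method = "gradcam", lesion = lt,
               grade = grade, correct = correct,
               hit = sample(c(TRUE, FALSE), n_img, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  manual <- do.call(rbind, lapply(lesions, function(lt) {
    data.frame(image_id = ids, method = "gradcam", lesion = lt,
               highlighted = rbinom(n_img, 1, 0.5), stringsAsFactors = FALSE)
  }))
  tab <- build_agreement_table(manual, records, lesions = lesions)
  for (i in seq_len(nrow(tab))) {
    in_stratum <- grade == tab$grade[i] & correct == tab$correct[i]
    sids <- ids[in_stratum]
    if (length(sids) == 0) {
      expect_identical(tab$status[i], "dash")
      next
    }
    m <- manual[manual$lesion == tab$lesion[i] &
                  manual$image_id %in% sids, ]
    r <- records[records$lesion == tab$lesion[i] &
                   records$image_id %in% sids, ]
    m <- m[order(m$image_id), ]; r <- r[order(r$image_id), ]
    a <- sum(m$highlighted == 1 & r$hit)
    b <- sum(m$highlighted == 1 & !r$hit)
    c_ <- sum(m$highlighted == 0 & r$hit)
    d <- sum(m$highlighted == 0 & !r$hit)
    want <- kappa_oracle_2x2(a, b, c_, d)
    if (is.na(want)) {
      expect_identical(tab$status[i], "na")
    } else {
      expect_equal(tab$kappa[i], want)
    }
  }
})

test_that("agreement table enforces matching image sets and renders dashes", {
  records <- data.frame(image_id = c("a", "b"), method = "gradcam",
                        lesion = "MA", grade = c(3L, 3L), correct = TRUE,
                        hit = c(TRUE, FALSE), stringsAsFactors = FALSE)
  manual_bad <- data.frame(image_id = c("a", "zzz"), method = "gradcam",
                           lesion = "MA", highlighted = c(1, 0),
                           stringsAsFactors = FALSE)
  expect_error(build_agreement_table(manual_bad, records),
               class = "fundusXAI_data_error")

  manual <- data.frame(image_id = c("a", "b"), method = "gradcam",
                       lesion = "MA", highlighted = c(1, 0),
                       stringsAsFactors = FALSE)
  tab <- build_agreement_table(manual, records)
  wide <- render_agreement_table(tab)
  expect_equal(tab$rendered[tab$correct & tab$grade == 3], "1.0000")
  expect_true(all(wide[wide$grade == 3, "incorrect_MA"] == "-"))
})
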
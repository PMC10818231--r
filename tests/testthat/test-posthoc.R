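g <- tiny_gazetteer()

test_that("duplicate-text tiers fire exactly at their boundaries", {
  mk <- function(texts) make_responses(length(texts),
                                       free_text_comment = texts)
  # 1 word repeated 100 times: flagged; 99 times: not
  expect_length(flag_duplicate_free_text(mk(rep("thanks", 100))), 100)
  expect_length(flag_duplicate_free_text(mk(rep("thanks", 99))), 0)
  # 2 words, 10 vs 9 repeats
  expect_length(flag_duplicate_free_text(mk(rep("great survey", 10))), 10)
  expect_length(flag_duplicate_free_text(mk(rep("great survey", 9))), 0)
  # 3 words, 3 repeats
  expect_length(flag_duplicate_free_text(mk(rep("no questions thanks", 3))), 3)
  expect_length(flag_duplicate_free_text(mk(rep("no questions thanks", 2))), 0)
  # empty texts never flagged, whatever their count
  expect_length(flag_duplicate_free_text(mk(rep("", 200))), 0)
})

test_that("duplicate-text flags match a hash-count oracle on a mixed corpus", {
  set.seed(31)
  texts <- c(
    rep("Thanks  a lot", 4),            # 3 words x 4 >= tier (3,3)
    rep("great survey", 12),            # 2 words x 12 >= tier (2,10)
    rep("ok", 30),                      # 1 word x 30 < 100: below tier
    sprintf("unique remark number %d", 1:40),
    rep("", 14)
  )
  texts <- sample(texts)
  resp <- make_responses(length(texts), free_text_comment = texts)
  oracle <- local({
    norm <- normalize_text(texts)
    counts <- table(norm[norm != ""])
    words <- lengths(strsplit(names(counts), " "))
    hot <- names(counts)[(words >= 1 & counts >= 100) |
                           (words >= 2 & counts >= 10) |
                           (words >= 3 & counts >= 3)]
    sort(resp$response_id[norm %in% hot])
  })
  expect_equal(flag_duplicate_free_text(resp), oracle)
  # order-invariance
  shuffled <- resp[sample(nrow(resp)), ]
  expect_equal(flag_duplicate_free_text(shuffled), oracle)
})

test_that("bad-IP strike needs positive VPN/data-center/offshore evidence", {
  r <- make_responses(5, ip_address = c("198.51.100.7",  # VPN prefix
                                        "192.0.2.200",   # offshore prefix
                                        "203.0.113.40",  # clean US prefix
                                        "8.8.8.8",       # unmatched
                                        "not-an-ip"))    # malformed
  expect_warning(flags <- flag_bad_ip(r, g), "malformed")
  expect_equal(flags, c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("longest prefix wins when IP ranges nest", {
  g2 <- gazetteer(
    addresses = tibble::tibble(address = "1 Oak St",
                               neighborhood = "Fishtown"),
    ip_intel = tibble::tibble(
      prefix = c("10.0.0.0/8", "10.9.0.0/16"),
      is_vpn = c(FALSE, TRUE),
      country = c("US", "US")
    ))
  r <- make_responses(2, ip_address = c("10.9.1.1", "10.8.1.1"))
  expect_equal(flag_bad_ip(r, g2), c(TRUE, FALSE))
})

test_that("screener inconsistency compares present items only", {
  r <- make_responses(4,
    scr_age = c(34, 34, 34, NA), main_age = c(34, 52, NA, 60),
    scr_zip = c("19104", "19104", "19147", "19104"),
    main_zip = c("19104", "19104", "19104", "19104"))
  expect_equal(flag_screener_inconsistency(r, c("age", "zip")),
               c(FALSE, TRUE, TRUE, FALSE))
  # numeric equality beats textual difference ("34" vs "34.0")
  r2 <- make_responses(1, scr_age = "34", main_age = "34.0")
  expect_false(flag_screener_inconsistency(r2, "age"))
  # items absent from the table are skipped entirely
  expect_false(flag_screener_inconsistency(r2, "nonexistent_item"))
})

test_that("k-strike verdicts follow the strike-count threshold", {
  strikes <- tibble::tibble(
    response_id = c("a", "a", "b", "c", "c", "c"),
    rule_id = c("dup_free_text", "bad_ip", "bad_ip",
                "dup_free_text", "bad_ip", "screener_inconsistency"))
  v2 <- apply_k_strike(strikes, 2)
  expect_equal(v2$label[v2$response_id == "a"], "fraud")
  expect_equal(v2$label[v2$response_id == "b"], "valid")
  v3 <- apply_k_strike(strikes, 3)
  expect_equal(v3$label[v3$response_id == "c"], "fraud")
  expect_equal(v3$label[v3$response_id == "a"], "valid")
  expect_error(apply_k_strike(strikes, 4), class = "surveysieve_config_error")
  # duplicated strike rows for the same criterion count once
  dup_rows <- strikes[c(3, 3, 3), ]
  expect_equal(apply_k_strike(dup_rows, 2)$label, "valid")
})

test_that("fraud sets are nested across k = 3, 2, 1", {
  co <- generate_cohort(cohort_spec(n_genuine = 120, seed = 8))
  rt <- apply_realtime_stage(co$responses, co$gazetteer, fd_config())
  surv <- co$responses[co$responses$response_id %in%
                         rt$labels$response_id[rt$labels$label == "valid"], ]
  fraud_at <- function(k) {
    ph <- apply_posthoc_stage(surv, co$gazetteer, fd_config(k_strike = k))
    ph$labels$response_id[ph$labels$label == "fraud"]
  }
  f1 <- fraud_at(1); f2 <- fraud_at(2); f3 <- fraud_at(3)
  expect_true(all(f3 %in% f2))
  expect_true(all(f2 %in% f1))
})

test_that("stage verdicts equal independent per-criterion evaluation", {
  co <- generate_cohort(cohort_spec(
    n_genuine = 150,
    archetype_counts = c(vpn_actor = 20, inconsistent_screener = 15),
    seed = 55))
  rt <- apply_realtime_stage(co$responses, co$gazetteer, fd_config())
  surv <- co$responses[co$responses$response_id %in%
                         rt$labels$response_id[rt$labels$label == "valid"], ]
  ph <- apply_posthoc_stage(surv, co$gazetteer, fd_config())
  dup <- surv$response_id %in% flag_duplicate_free_text(surv)
  ip <- flag_bad_ip(surv, co$gazetteer)
  inc <- flag_screener_inconsistency(surv, fd_config()$key_items)
  expected <- surv$response_id[(dup + ip + inc) >= 2]
  expect_setequal(ph$labels$response_id[ph$labels$label == "fraud"], expected)
  expect_equal(ph$counts_by_rule$n,
               c(sum(dup), sum(ip), sum(inc)))
})
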
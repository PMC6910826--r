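test_that("LIM-domain count alone sets the growing/blocking class", {
  expect_equal(classify_isoform(0:4),
               c("blocking", "blocking", "growing", "growing", "growing"))
  # archetypes: a 4-LIM isoform grows, 1- and 0-LIM isoforms block
  rec <- isoform_records(
    transcript_id = c("Zasp52-PR", "Zasp52-PK", "Zasp66-PH"),
    gene = c("Zasp52", "Zasp52", "Zasp66"),
    n_lim = c(4L, 1L, 0L))
  expect_equal(classify_isoform(rec), c("growing", "blocking", "blocking"))
  # permutation equivariance
  set.seed(2)
  n <- sample(0:6, 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(classify_isoform(n)[perm], classify_isoform(n[perm]))
  expect_error(isoform_records(c("a", "a"), "g", c(1, 2)), "unique")
})

test_that("class time-courses average member transcripts per timepoint", {
  rec <- isoform_records(c("g1", "b1"), c("Zasp52", "Zasp66"), c(3L, 0L))
  tpm <- rbind(g1 = c(5, 50, 100), b1 = c(0, 1, 80))
  expr <- isoform_expression_set(tpm, c(24, 48, 72), rec)
  tc <- class_timecourse(expr)
  expect_equal(tc$mean_tpm[tc$class == "growing"], c(5, 50, 100))
  expect_equal(tc$mean_tpm[tc$class == "blocking"], c(0, 1, 80))
  expect_equal(tc$mean_log_tpm, log10(tc$mean_tpm + 1))
  expect_true(all(tc$n_isoforms == 1L))

  zero <- isoform_expression_set(rbind(b1 = c(0, 0)), c(24, 48),
                                 isoform_records("b1", "Zasp66", 0L))
  expect_warning(tz <- class_timecourse(zero), "growing")
  expect_equal(tz$mean_log_tpm, c(0, 0))
})

test_that("class means are invariant to ordering and class-mean additions", {
  sim <- make_expression_timecourse(expression_sim_params(seed = 4L))
  tc <- class_timecourse(sim$expr)
  perm <- sample(nrow(sim$expr$tpm))
  expr_p <- isoform_expression_set(sim$expr$tpm[perm, ],
                                   sim$expr$timepoints_h,
                                   sim$expr$records[perm, ])
  expect_equal(class_timecourse(expr_p), tc)
  # adding a transcript at the growing-class mean leaves that mean fixed
  gmean <- tc$mean_tpm[tc$class == "growing"]
  tpm2 <- rbind(sim$expr$tpm, gnew = gmean)
  rec2 <- rbind(sim$expr$records,
                data.frame(transcript_id = "gnew", gene = "Zasp52",
                           n_lim = 3L, has_zm = TRUE, has_pdz = TRUE))
  tc2 <- class_timecourse(isoform_expression_set(tpm2,
                                                 sim$expr$timepoints_h,
                                                 rec2))
  expect_equal(tc2$mean_tpm[tc2$class == "growing"], gmean)
})

test_that("onset is the interpolated half-plateau crossing", {
  tc <- data.frame(class = "growing", timepoint_h = c(16, 24, 32, 48),
                   mean_tpm = c(0, 0, 100, 100))
  expect_equal(unname(onset_time(tc)), 28)
  expect_equal(unname(onset_time(tc, fraction_of_plateau = 0.25)), 26)
  flat <- data.frame(class = "blocking", timepoint_h = c(16, 24),
                     mean_tpm = c(0, 0))
  expect_message(o <- onset_time(flat), "flat")
  expect_true(is.na(o))
})

test_that("onset recovery error is below one timepoint spacing without noise", {
  p <- expression_sim_params(lognormal_sd = 0)
  tc <- class_timecourse(make_expression_timecourse(p)$expr)
  on <- onset_time(tc)
  spacing <- max(diff(p$timepoints_h))
  expect_lt(abs(on[["growing"]] - 24), spacing)
  expect_lt(abs(on[["blocking"]] - 60), spacing)
  expect_lt(on[["growing"]], on[["blocking"]])
})

test_that("TPM tables and annotations round-trip through files", {
  sim <- make_expression_timecourse(expression_sim_params(
    n_growing = 3, n_blocking = 3, seed = 8L))
  td <- withr::local_tempdir()
  tpm_path <- file.path(td, "tpm.csv")
  ann_path <- file.path(td, "annotation.csv")
  df <- data.frame(transcript_id = rownames(sim$expr$tpm),
                   sim$expr$tpm, check.names = FALSE)
  utils::write.csv(df, tpm_path, row.names = FALSE)
  utils::write.csv(sim$expr$records, ann_path, row.names = FALSE)
  back <- read_isoform_tpm(tpm_path, ann_path)
  expect_equal(back$tpm, sim$expr$tpm)
  expect_equal(back$timepoints_h, sim$expr$timepoints_h)
  expect_equal(back$records$n_lim, sim$expr$records$n_lim)
  bad <- file.path(td, "bad.csv")
  utils::write.csv(data.frame(transcript_id = "t1", early = 1), bad,
                   row.names = FALSE)
  expect_error(read_isoform_tpm(bad, ann_path), "hours")
})
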
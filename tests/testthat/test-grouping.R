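test_that("sleep-onset latency is the first NREM epoch start", {
  expect_equal(sleep_onset_latency(hypnogram(c(rep("wake", 5), "NREM"))), 20)
  expect_equal(sleep_onset_latency(hypnogram(c("NREM", "wake"))), 0)
  expect_true(is.na(sleep_onset_latency(hypnogram(rep("wake", 10)))))
})

test_that("pure slow LFP with low EMG scores as NREM throughout", {
  fs <- 250
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  lfp <- continuous_signal(60 * sin(2 * pi * 2 * t), fs)
  set.seed(1)
  emg <- continuous_signal(rnorm(length(t), sd = 10), fs)
  h <- score_vigilance(lfp, emg)
  expect_true(all(h$labels == "NREM"))
})

test_that("clipped epochs are scored as artifact", {
  fs <- 250
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- 60 * sin(2 * pi * 2 * t)
  x[round(10 * fs):round(11 * fs)] <- 6000   # saturation plateau
  set.seed(2)
  emg <- continuous_signal(rnorm(length(t), sd = 10), fs)
  h <- score_vigilance(continuous_signal(x, fs), emg)
  expect_equal(h$labels[3], "artifact")   # the 10-11 s plateau sits in epoch 3
  expect_true(all(h$labels[10:20] == "NREM"))
})

test_that("scorer recovers generator ground truth on default sessions", {
  ag <- vapply(1:3, function(k) {
    s <- simulate_session(gen_params(duration = 400), seed = k)
    h <- score_vigilance(s$prl, s$emg)
    mean(h$labels == s$hypnogram$labels)
  }, numeric(1L))
  expect_gt(mean(ag), 0.85)
})

test_that("event metrics: density arithmetic and empty-window flags", {
  ev <- event_table(kind = rep("slow_wave", 24),
                    start = seq(10, 1000, length.out = 24),
                    end = seq(10, 1000, length.out = 24) + 1,
                    peak_time = seq(10, 1000, length.out = 24) + 0.7,
                    amplitude = 100, intrinsic_freq = 1)
  m <- event_metrics(ev, c(0, 1200))          # 20 min window
  sw <- m[m$kind == "slow_wave", ]
  expect_equal(sw$density, 1.2)
  expect_equal(sw$n, 24L)
  empty <- event_metrics(ev, c(2000, 3200))
  expect_true(all(empty$density == 0))
  expect_true(all(is.na(empty$amplitude)))
})

test_that("state amounts and windowed metrics split baseline from post", {
  h <- hypnogram(c(rep("wake", 10), rep("NREM", 20)))   # 40 s + 80 s
  expect_equal(state_amounts(h, c(0, 120))[["NREM"]], 80)
  expect_equal(state_amounts(h, c(20, 60))[["wake"]], 20)

  ev <- event_table(kind = c("spindle", "spindle"), start = c(10, 70),
                    end = c(11, 71), peak_time = c(10.5, 70.5),
                    amplitude = c(40, 60), intrinsic_freq = 12)
  man <- session_manifest("s1", "custom", injection_time = 60,
                          baseline_window = c(0, 60), post_window = c(60, 120))
  wm <- windowed_metrics(ev, h, man)
  expect_equal(wm$baseline$events$n[wm$baseline$events$kind == "spindle"], 1L)
  expect_equal(wm$post$events$amplitude[wm$post$events$kind == "spindle"], 60)

  # with a signal and spike trains the windows also carry spectra and units
  set.seed(20)
  sig <- continuous_signal(rnorm(120 * 250) * 20, 250, region = "PrL")
  trains <- list(spike_train(sort(runif(300, 0, 120)), "u1", "PrL", 300))
  wm2 <- windowed_metrics(ev, h, man, signal = sig, spike_trains = trains)
  expect_s3_class(wm2$baseline$spectrum, "power_spectrum")
  expect_equal(wm2$post$units$fr,
               sum(trains[[1]]$times >= 60 & trains[[1]]$times < 120) / 60)
})

test_that("change records agree in sign across modes for positive baselines", {
  base <- c(a = 2, b = 5, c = 1.5)
  post <- c(a = 3, b = 4, c = 1.5)
  d <- change_records(base, post, "difference")
  p <- change_records(base, post, "percent")
  expect_equal(sign(d$change), sign(p$change))
  expect_equal(p$change[1], 50)
  z <- change_records(c(a = 0), c(a = 1), "percent")
  expect_true(is.na(z$change))
})

test_that("identical values across groups short-circuit to p = 1", {
  d <- data.frame(condition = rep(c("saline", "zolpidem", "diazepam"), each = 4),
                  value = 1)
  out <- compare_groups(d)
  expect_equal(out$p, 1)
  expect_true(all(out$posthoc$p_adj == 1))
})

test_that("group sizes below 3 are an error naming the group", {
  d <- data.frame(condition = c(rep("saline", 4), rep("zolpidem", 2)),
                  value = rnorm(6))
  expect_error(compare_groups(d), "zolpidem")
})

test_that("a 5-SD shifted group is flagged against saline by the post-hoc", {
  set.seed(14)
  res <- replicate(40, {
    d <- data.frame(
      condition = rep(c("saline", "zolpidem", "diazepam", "THIP"), each = 5),
      value = rnorm(20))
    d$value[d$condition == "zolpidem"] <- d$value[d$condition == "zolpidem"] + 5
    out <- compare_groups(d)
    ph <- out$posthoc
    c(hit = out$p < 0.05 && ph$p_adj[ph$condition == "zolpidem"] < 0.05,
      false_flag = any(ph$p_adj[ph$condition != "zolpidem"] < 0.05))
  })
  expect_gte(mean(res["hit", ]), 0.95)
  expect_lte(mean(res["false_flag", ]), 0.2)   # adjusted level holds roughly
})

test_that("the decision tree is deterministic and adjusted p >= raw p", {
  set.seed(15)
  d <- data.frame(condition = rep(c("saline", "drugA", "drugB"), each = 6),
                  value = c(rnorm(6), rexp(6), rnorm(6)))
  o1 <- compare_groups(d); o2 <- compare_groups(d)
  expect_identical(o1$test, o2$test)
  expect_equal(o1$p, o2$p)
  expect_true(all(o1$posthoc$p_adj >= o1$posthoc$p_raw - 1e-12))
  # heavy-tailed data route to Kruskal-Wallis + Dunn
  d2 <- data.frame(condition = rep(c("saline", "drugA", "drugB"), each = 8),
                   value = rt(24, df = 1))
  expect_equal(compare_groups(d2)$test, "kruskal_dunn")
  # clean Gaussian equal-variance data route to ANOVA + Bonferroni
  set.seed(16)
  d3 <- data.frame(condition = rep(c("saline", "drugA"), each = 30),
                   value = rnorm(60))
  expect_equal(compare_groups(d3)$test, "anova_bonferroni")
})

test_that("PAC comparisons use one-sample and Welch t-tests", {
  set.seed(17)
  d <- data.frame(condition = rep(c("saline", "zolpidem"), each = 5),
                  value = c(rnorm(5, 0, 0.3), rnorm(5, 3, 1)))
  out <- compare_pac(d)
  zl <- out[out$condition == "zolpidem", ]
  expect_lt(zl$p_vs0, 0.05)
  expect_lt(zl$p_vs_ref, 0.05)
  expect_true(is.na(out$p_vs_ref[out$condition == "saline"]))
  # agreement with stats::t.test directly
  ref <- t.test(d$value[d$condition == "zolpidem"],
                d$value[d$condition == "saline"], var.equal = FALSE)
  expect_equal(zl$p_vs_ref, ref$p.value)
})

test_that("per-bin spectral comparison reduces to compare_groups on one bin", {
  set.seed(18)
  d <- data.frame(freq = 1, condition = rep(c("saline", "drugA"), each = 5),
                  value = rnorm(10, 100, 10))
  out <- per_bin_spectral_comparison(d)
  direct <- compare_groups(d[, c("condition", "value")])
  expect_equal(out$p, direct$p)
  bad <- rbind(d, data.frame(freq = 2, condition = "saline", value = 100))
  expect_error(per_bin_spectral_comparison(bad), "grid")
})

test_that("null per-bin comparisons produce ~alpha false positives, none after Bonferroni", {
  set.seed(19)
  nb <- 40
  d <- do.call(rbind, lapply(seq_len(nb), function(f)
    data.frame(freq = f, condition = rep(c("saline", "a", "b"), each = 5),
               value = rnorm(15, 100, 10))))
  out <- per_bin_spectral_comparison(d)
  expect_lt(mean(out$sig_raw), 0.2)          # ~0.05 expected, loose bound
  expect_lte(sum(out$sig_bonf), 1L)
})
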
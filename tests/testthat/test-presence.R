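make_decisions <- function(file_ids, counted_lfc) {
  data.frame(file_id = rep(file_ids, each = 3),
             band = rep(c("lfc", "hfc86", "hfc99"), length(file_ids)),
             raw_detected = FALSE,
             counted = as.vector(rbind(counted_lfc, FALSE, FALSE)),
             stringsAsFactors = FALSE)
}

test_that("daily percentages and gaps come out right", {
  ids <- sprintf("f%03d", 1:144)
  cal <- data.frame(file_id = ids, date = as.Date("2013-03-01"))
  dec <- make_decisions(ids, c(rep(TRUE, 72), rep(FALSE, 72)))
  daily <- aggregate_daily(dec, data.frame(file_id = character()), cal)
  lfc <- daily[daily$band == "lfc", ]
  expect_equal(lfc$pct, 50.0)
  expect_equal(lfc$n_files, 144L)
  # a gap day inside the calendar range
  cal2 <- rbind(cal, data.frame(file_id = "g1", date = as.Date("2013-03-03")))
  dec2 <- rbind(dec, make_decisions("g1", FALSE))
  daily2 <- aggregate_daily(dec2, data.frame(file_id = character()), cal2)
  gap_day <- daily2[daily2$band == "lfc" & daily2$date == as.Date("2013-03-02"), ]
  expect_true(gap_day$data_gap)
  expect_true(is.na(gap_day$pct))
  expect_error(aggregate_daily(dec, data.frame(file_id = character()),
                               rbind(cal, cal[1, ])), "duplicate")
})

test_that("counted days equal the injected-chorus days across a month", {
  set.seed(501)
  days <- seq(as.Date("2013-03-01"), as.Date("2013-03-30"), by = "day")
  injected <- days >= as.Date("2013-03-10") & days <= as.Date("2013-03-20")
  ids <- c(); dates <- c(); counted <- c()
  for (i in seq_along(days)) {
    day_ids <- sprintf("%s_%03d", format(days[i]), 1:12)
    ids <- c(ids, day_ids); dates <- c(dates, rep(days[i], 12))
    # injected days: most files counted; others: none
    counted <- c(counted, if (injected[i]) runif(12) < 0.9 else rep(FALSE, 12))
  }
  cal <- data.frame(file_id = ids, date = as.Date(dates, origin = "1970-01-01"))
  daily <- aggregate_daily(make_decisions(ids, counted),
                           data.frame(file_id = character()), cal)
  lfc <- daily[daily$band == "lfc", ]
  expect_identical(lfc$n_counted > 0, injected)
})

test_that("three-day running mean matches arithmetic and the convolution oracle", {
  expect_equal(running_mean3(rep(7, 10)), rep(7, 10))
  expect_equal(running_mean3(c(0, 0, 100, 0, 0)),
               c(0, 100 / 3, 100 / 3, 100 / 3, 0))
  set.seed(502)
  x <- runif(50, 0, 100)
  oracle <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  oracle[1] <- mean(x[1:2]); oracle[50] <- mean(x[49:50])
  expect_equal(running_mean3(x), oracle, tolerance = 1e-12)
  # gaps break the window and stay NA
  xg <- c(1, 2, NA, 4, 5)
  sm <- running_mean3(xg)
  expect_true(is.na(sm[3]))
  expect_equal(sm[2], 1.5)   # only observed neighbours
  expect_equal(sm[4], 4.5)
  # mean preserved on gap-free interior
  expect_equal(mean(running_mean3(x)[2:49]), mean(x[2:49]), tolerance = 0.05)
})

test_that("the chorus FPR line is 3% of a 144-file day", {
  refs <- fpr_reference()
  expect_equal(refs$chorus_line_files_per_day, 4.32)
  expect_equal(round(refs$chorus_line_files_per_day, 1), 4.3)
  expect_equal(refs$pulse_line_per_day, 575)
})

test_that("isolated exceedances are flagged; sustained seasons are not", {
  days <- seq(as.Date("2013-06-01"), by = "day", length.out = 30)
  n_counted <- rep(0L, 30)
  n_counted[c(5, 15, 25)] <- 10L          # three planted isolated exceedances
  n_counted[18:22] <- 30L                 # a sustained presence period
  daily <- data.frame(site_id = "s", date = days, band = "lfc",
                      n_files = 144L, n_counted = n_counted,
                      pct = 100 * n_counted / 144, data_gap = FALSE,
                      n_pulses = 0L)
  flags <- flag_outlier_days(daily, fpr_reference(), "chorus")
  expect_identical(nrow(flags), 3L)
  expect_identical(flags$date, days[c(5, 15, 25)])
  # pulse-count flags use the 575/day line
  daily$n_pulses <- ifelse(seq_len(30) == 7, 800L, 100L)
  pflags <- flag_outlier_days(daily, fpr_reference(), "pulses")
  expect_identical(pflags$date, days[7])
})

test_that("site mean SNR averages counted files only", {
  dec <- data.frame(site_id = rep(c("A", "B"), each = 4),
                    band = "lfc", snr_db = c(6, 6, 6, 2, 3, 3, 3, 3),
                    counted = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  sm <- site_mean_snr(dec)
  expect_equal(sm$mean_snr_db[sm$site_id == "A"], 6)
  expect_equal(sm$mean_snr_db[sm$site_id == "B"], 3)
  expect_gt(sm$mean_snr_db[sm$site_id == "A"],
            sm$mean_snr_db[sm$site_id == "B"])
  # empty site: sentinel
  dec2 <- rbind(dec, data.frame(site_id = "C", band = "lfc", snr_db = 9,
                                counted = FALSE))
  smc <- site_mean_snr(dec2)
  expect_true(is.na(smc$mean_snr_db[smc$site_id == "C"]))
})

test_that("band counts are independent: their sum may exceed n_files", {
  ids <- sprintf("f%d", 1:4)
  dec <- data.frame(file_id = rep(ids, each = 3),
                    band = rep(c("lfc", "hfc86", "hfc99"), 4),
                    raw_detected = TRUE, counted = TRUE)
  cal <- data.frame(file_id = ids, date = as.Date("2013-03-01"))
  daily <- aggregate_daily(dec, data.frame(file_id = character()), cal)
  expect_gt(sum(daily$n_counted), unique(daily$n_files))
})
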
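presence3 <- function(np = 10, ids = c("V01", "V02", "V03")) {
  matrix(1L, length(ids), np, dimnames = list(ids, NULL))
}

scan_row <- function(day, a, r, nn = 4, fd = 20) {
  sprintf("2008-07-%02d 08:00:00,scan,proximity,%s,%s,%s,%s", day, a, r, nn, fd)
}

test_that("proximity index is periods-linked over periods-joint", {
  rows <- vapply(1:10, function(d) scan_row(d, "V01", "V02"), character(1))
  log <- read_event_log(write_event_csv(rows))
  net <- proximity_association(log, presence3())
  expect_equal(net$matrix$values["V01", "V02"], 1.0)

  rows2 <- vapply(1:3, function(d) scan_row(d, "V01", "V02"), character(1))
  rows2 <- c(rows2, vapply(4:10, function(d)
    scan_row(d, "V01", "V03"), character(1)))
  net2 <- proximity_association(read_event_log(write_event_csv(rows2)),
                                presence3())
  expect_equal(net2$matrix$values["V01", "V02"], 0.3)
})

test_that("scans near the feeders or beyond 10 m are excluded", {
  rows <- c(scan_row(1, "V01", "V02", fd = 5),    # at the feeders
            scan_row(2, "V01", "V02", nn = 12),   # neighbour too far
            scan_row(3, "V01", "V02", fd = 20))   # qualifies
  net <- proximity_association(read_event_log(write_event_csv(rows)),
                               presence3())
  expect_equal(net$matrix$values["V01", "V02"], 1 / 10)
  # boundary: exactly 10 m from the feeders does not qualify; 10 m
  # neighbour distance does
  rows_b <- c(scan_row(1, "V01", "V02", fd = 10),
              scan_row(2, "V01", "V02", nn = 10, fd = 11))
  net_b <- proximity_association(read_event_log(write_event_csv(rows_b)),
                                 presence3())
  expect_equal(net_b$matrix$values["V01", "V02"], 1 / 10)
})

test_that("proximity scoring ignores record order and duplicate scans", {
  rows <- c(scan_row(1, "V01", "V02"), scan_row(1, "V02", "V01"),
            scan_row(1, "V01", "V02"))
  net <- proximity_association(read_event_log(write_event_csv(rows)),
                               presence3(np = 1))
  expect_equal(net$matrix$values["V01", "V02"], 1.0)
  expect_equal(sum(net$occurrence$x) / 2, 1)
})

test_that("dyads never jointly observable give a missing index", {
  pres <- presence3(np = 4)
  pres["V02", ] <- c(1L, 1L, 0L, 0L)
  pres["V03", ] <- c(0L, 0L, 1L, 1L)
  log <- read_event_log(write_event_csv(scan_row(1, "V01", "V02")))
  net <- proximity_association(log, pres)
  expect_true(is.na(net$matrix$values["V02", "V03"]))
  expect_equal(net$matrix$values["V01", "V02"], 1 / 2)
})

test_that("interaction rates count bouts with direction collapsed", {
  rows <- c(
    sprintf("2008-07-01 08:%02d:00,bout,allogroom,V01,V02,0.5,20", 0:2),
    sprintf("2008-07-01 09:%02d:00,bout,allogroom,V02,V01,0.5,20", 0:1),
    "2008-07-01 10:00:00,bout,play,V01,V03,0.5,20")
  log <- read_event_log(write_event_csv(rows))
  net <- interaction_rate(log, c("allogroom", "contact_sit", "play"),
                          presence3(np = 1))
  expect_equal(net$matrix$values["V01", "V02"], 5)
  expect_equal(net$matrix$values["V01", "V03"], 1)
  expect_equal(net$n_events, 6)
  expect_error(interaction_rate(log, character(0), presence3(1)), "empty")
})

test_that("a log without cooperation gives an empty cooperation network", {
  rows <- scan_row(1, "V01", "V02")
  log <- read_event_log(write_event_csv(rows))
  net <- cooperation_network(log, presence3(np = 1))
  expect_equal(net$n_events, 0)
  expect_true(all(net$matrix$values == 0, na.rm = TRUE))
})

test_that("the between-class mask selects exactly small x large dyads", {
  r5 <- tiny_roster(7, n_small = 2)   # 2 small + 5 large
  m5 <- between_class_mask(r5)
  expect_equal(sum(m5$values) / 2, 10)
  r11 <- tiny_roster(13, n_small = 2) # 2 small + 11 large
  expect_equal(sum(between_class_mask(r11)$values) / 2, 22)
  # sum of unmasked cells double-counts unordered dyads
  expect_equal(sum(m5$values), 2 * 2 * 5)
  all_large <- tiny_roster(5, n_small = 0)
  expect_true(all(between_class_mask(all_large)$values == 0))
  bad <- r5
  bad$coop_class[2] <- NA
  expect_error(between_class_mask(bad), "missing")
})
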
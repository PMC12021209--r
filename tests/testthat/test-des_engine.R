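test_that("events fire in (time, priority, insertion) order", {
  sim <- sim_new()
  fired <- character(0)
  on_event(sim, "a", function(sim, ev) fired <<- c(fired, ev$payload$tag))
  schedule(sim, 10, "a", list(tag = "late"))
  schedule(sim, 5, "a", list(tag = "first-in"))
  schedule(sim, 5, "a", list(tag = "second-in"))
  schedule(sim, 5, "a", list(tag = "high-priority"), priority = -1L)
  run_until(sim, 100)
  expect_equal(fired, c("high-priority", "first-in", "second-in", "late"))
  expect_equal(sim$clock, 100)
})

test_that("an empty calendar returns immediately with the clock advanced", {
  sim <- sim_new()
  log <- run_until(sim, 250)
  expect_equal(nrow(log), 0L)
  expect_equal(sim$clock, 250)
})

test_that("a three-event toy run reproduces the hand-written log", {
  sim <- sim_new()
  on_event(sim, "arrive", function(sim, ev) {
    schedule(sim, sim$clock + 7, "depart")
  })
  on_event(sim, "depart", function(sim, ev) NULL)
  schedule(sim, 3, "arrive")
  schedule(sim, 5, "arrive")
  log <- run_until(sim, 50)
  expected <- data.frame(
    time = c(3, 5, 10, 12),
    kind = c("arrive", "arrive", "depart", "depart"),
    seq = c(1L, 2L, 3L, 4L))
  expect_equal(log, expected)
})

test_that("scheduling in the past is rejected", {
  sim <- sim_new()
  on_event(sim, "x", function(sim, ev) NULL)
  schedule(sim, 10, "x")
  run_until(sim, 20)
  expect_error(schedule(sim, 15, "x"), "before current clock")
})

test_that("a full single server queues the second request (M/D/1 hand case)", {
  sim <- sim_new()
  pool <- resource_pool("srv", 1L)
  done <- numeric(0)
  on_event(sim, "go", function(sim, ev) {
    seize(sim, pool, ev$payload$id, 10,
          on_complete = function(sim, entity) done <<- c(done, sim$clock))
  })
  schedule(sim, 0, "go", list(id = 1))
  schedule(sim, 0, "go", list(id = 2))
  run_until(sim, 100)
  expect_equal(done, c(10, 20))
  expect_equal(pool$busy_time, 20)
  expect_equal(pool$waits, c(0, 10))
})

test_that("an always-idle pool has zero utilisation", {
  pool <- resource_pool("idle", 3L)
  pool_open(pool, 480)
  expect_equal(pool_utilisation(pool), 0)
})

test_that("seize matches an independent single-server queue recursion", {
  # oracle: W_k = max(0, C_{k-1} - a_k), C_k = max(a_k, C_{k-1}) + s_k
  streams <- rng_streams(99, "q")
  arrivals <- cumsum(with_stream(streams, "q", stats::rexp(40, 1 / 12)))
  services <- with_stream(streams, "q", stats::runif(40, 2, 18))
  comp <- numeric(40); wait <- numeric(40)
  prev <- 0
  for (k in seq_len(40)) {
    wait[k] <- max(0, prev - arrivals[k])
    comp[k] <- max(arrivals[k], prev) + services[k]
    prev <- comp[k]
  }
  sim <- sim_new()
  pool <- resource_pool("srv", 1L)
  on_event(sim, "arr", function(sim, ev) {
    seize(sim, pool, ev$payload$k, ev$payload$s)
  })
  for (k in seq_len(40)) {
    schedule(sim, arrivals[k], "arr", list(k = k, s = services[k]))
  }
  run_until(sim, max(comp) + 1)
  expect_equal(pool$waits, wait, tolerance = 1e-10)
  # conservation: busy time equals the sum of service durations
  expect_equal(pool$busy_time, sum(services), tolerance = 1e-10)
})

test_that("a stationary single queue satisfies Little's law approximately", {
  streams <- rng_streams(7, "q")
  n <- 4000
  lambda <- 1 / 10
  arrivals <- cumsum(with_stream(streams, "q", stats::rexp(n, lambda)))
  services <- with_stream(streams, "q", stats::rexp(n, 1 / 6))
  sim <- sim_new()
  pool <- resource_pool("srv", 1L)
  sojourn <- numeric(0)
  on_event(sim, "arr", function(sim, ev) {
    t0 <- ev$time
    seize(sim, pool, ev$payload$k, ev$payload$s,
          on_complete = function(sim, entity) {
            sojourn <<- c(sojourn, sim$clock - t0)
          })
  })
  for (k in seq_len(n)) {
    schedule(sim, arrivals[k], "arr", list(k = k, s = services[k]))
  }
  run_until(sim, arrivals[n] + 10000)
  horizon <- sim$clock
  L <- sum(sojourn) / horizon        # time-average number in system
  W <- mean(sojourn)
  lam_hat <- n / horizon
  expect_lt(abs(L - lam_hat * W) / L, 0.01)
})

test_that("named substreams are reproducible and mutually independent", {
  s1 <- rng_streams(123, c("a", "b"))
  s2 <- rng_streams(123, c("a", "b"))
  x1 <- with_stream(s1, "a", stats::runif(5))
  # consuming stream b must not perturb stream a
  invisible(with_stream(s2, "b", stats::runif(1000)))
  x2 <- with_stream(s2, "a", stats::runif(5))
  expect_identical(x1, x2)
  y1 <- with_stream(s1, "a", stats::runif(3))
  y2 <- with_stream(s2, "a", stats::runif(3))
  expect_identical(y1, y2)
  expect_error(with_stream(s1, "nope", stats::runif(1)), "unknown substream")
})
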
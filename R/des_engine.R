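# Discrete-event kernel: event calendar, simulation clock, capacitated
# resource pools with FIFO queueing and busy-time accounting, and named
# reproducible random streams.

#' Create a discrete-event simulation environment
#'
#' The simulation environment holds the event calendar, the clock (integer or
#' fractional minutes from time zero), registered event handlers and the event
#' log. Events are executed in (time, priority, insertion order) order.
#'
#' @param start_time Clock value at creation (minutes, default 0).
#' @return An environment of class `rs_sim`.
#' @seealso [schedule()], [run_until()], [resource_pool()]
#' @export
#' @examples
#' sim <- sim_new()
#' on_event(sim, "ping", function(sim, ev) NULL)
#' schedule(sim, 10, "ping")
#' log <- run_until(sim, 100)
sim_new <- function(start_time = 0) {
  sim <- new.env(parent = emptyenv())
  sim$clock <- start_time
  # calendar as parallel vectors; extraction scans for the minimum key
  sim$ev_time <- numeric(0)
  sim$ev_prio <- integer(0)
  sim$ev_seq <- integer(0)
  sim$ev_kind <- character(0)
  sim$ev_payload <- list()
  sim$seq_counter <- 0L
  sim$handlers <- list()
  sim$log <- list()
  sim$n_logged <- 0L
  class(sim) <- c("rs_sim", "environment")
  sim
}

#' Register an event handler
#'
#' @param sim A simulation environment from [sim_new()].
#' @param kind Event kind (character scalar).
#' @param fun Function `(sim, event)` called when an event of this kind fires.
#' @return The simulation environment, invisibly.
#' @export
on_event <- function(sim, kind, fun) {
  stopifnot(is.character(kind), length(kind) == 1L, is.function(fun))
  sim$handlers[[kind]] <- fun
  invisible(sim)
}

#' Schedule an event
#'
#' Events may not be scheduled in the past. Ties in time are broken by
#' `priority` (lower fires first), then insertion order.
#'
#' @param sim A simulation environment.
#' @param time Absolute simulation time (minutes).
#' @param kind Event kind; a handler of that kind must be registered before
#'   [run_until()] reaches the event.
#' @param payload Arbitrary payload stored with the event.
#' @param priority Integer tie-breaker, lower first (default 0).
#' @return Invisibly, the sequence number of the scheduled event.
#' @export
schedule <- function(sim, time, kind, payload = NULL, priority = 0L) {
  if (time < sim$clock) {
    stop("cannot schedule event at time ", time, " before current clock ",
         sim$clock)
  }
  sim$seq_counter <- sim$seq_counter + 1L
  i <- length(sim$ev_time) + 1L
  sim$ev_time[i] <- time
  sim$ev_prio[i] <- as.integer(priority)
  sim$ev_seq[i] <- sim$seq_counter
  sim$ev_kind[i] <- kind
  sim$ev_payload[[i]] <- if (is.null(payload)) list() else payload
  invisible(sim$seq_counter)
}

next_event_index <- function(sim) {
  if (length(sim$ev_time) == 0L) return(0L)
  tmin <- min(sim$ev_time)
  cand <- which(sim$ev_time == tmin)
  if (length(cand) > 1L) {
    pmin <- min(sim$ev_prio[cand])
    cand <- cand[sim$ev_prio[cand] == pmin]
    if (length(cand) > 1L) cand <- cand[which.min(sim$ev_seq[cand])]
  }
  cand[1L]
}

#' Run the simulation until a given time
#'
#' Executes all events with time <= `t_end` in (time, priority, insertion
#' order) order, advancing the clock. When the calendar empties the clock
#' jumps to `t_end`.
#'
#' @param sim A simulation environment.
#' @param t_end Stop time (minutes); must be >= the current clock.
#' @return The event log: a data frame with one row per executed event
#'   (`time`, `kind`, `seq`), replayable given the same seeds and handlers.
#' @export
run_until <- function(sim, t_end) {
  if (t_end < sim$clock) stop("t_end precedes current clock")
  repeat {
    i <- next_event_index(sim)
    if (i == 0L || sim$ev_time[i] > t_end) break
    ev <- list(time = sim$ev_time[i], kind = sim$ev_kind[i],
               seq = sim$ev_seq[i], priority = sim$ev_prio[i],
               payload = sim$ev_payload[[i]])
    # remove before dispatch so handlers can schedule freely
    keep <- seq_along(sim$ev_time) != i
    sim$ev_time <- sim$ev_time[keep]
    sim$ev_prio <- sim$ev_prio[keep]
    sim$ev_seq <- sim$ev_seq[keep]
    sim$ev_kind <- sim$ev_kind[keep]
    sim$ev_payload <- sim$ev_payload[keep]
    sim$clock <- ev$time
    sim$n_logged <- sim$n_logged + 1L
    sim$log[[sim$n_logged]] <- ev[c("time", "kind", "seq")]
    h <- sim$handlers[[ev$kind]]
    if (is.null(h)) stop("no handler registered for event kind '", ev$kind, "'")
    h(sim, ev)
  }
  sim$clock <- max(sim$clock, t_end)
  event_log(sim)
}

#' Extract the event log as a data frame
#'
#' @param sim A simulation environment.
#' @return Data frame with columns `time`, `kind`, `seq`.
#' @export
event_log <- function(sim) {
  if (sim$n_logged == 0L) {
    return(data.frame(time = numeric(0), kind = character(0),
                      seq = integer(0)))
  }
  lg <- sim$log[seq_len(sim$n_logged)]
  data.frame(
    time = vapply(lg, `[[`, numeric(1), "time"),
    kind = vapply(lg, `[[`, character(1), "kind"),
    seq = vapply(lg, `[[`, integer(1), "seq")
  )
}

# ---- resource pools ---------------------------------------------------------

#' Create a capacitated resource pool
#'
#' A pool serves at most `capacity` entities simultaneously; further requests
#' wait in a FIFO queue. Busy time (entity-minutes of service) and open time
#' (minutes the pool was available) accumulate for utilisation reporting.
#'
#' @param name Pool name.
#' @param capacity Integer capacity >= 0.
#' @return An environment of class `rs_pool`.
#' @export
resource_pool <- function(name, capacity) {
  stopifnot(capacity >= 0)
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$capacity <- as.integer(capacity)
  p$in_service <- 0L
  p$queue <- list()    # FIFO of pending requests
  p$busy_time <- 0
  p$open_time <- 0
  p$waits <- numeric(0)  # queue-wait per served entity
  class(p) <- c("rs_pool", "environment")
  p
}

#' Request a resource from a pool (seize) for a fixed service duration
#'
#' If a server is free, service starts immediately and a completion event
#' (`kind = "release"`, handled internally) is scheduled after `duration`
#' minutes. Otherwise the request queues FIFO and starts when a server frees.
#' Queue waits are recorded per entity; busy time increases by exactly the
#' service duration on completion.
#'
#' @param sim Simulation environment (its `"release"` handler is installed on
#'   first use).
#' @param pool A pool from [resource_pool()].
#' @param entity Identifier recorded with the request.
#' @param duration Service duration in minutes (> 0).
#' @param on_complete Optional callback `(sim, entity)` run at completion.
#' @return Invisibly `TRUE`.
#' @export
seize <- function(sim, pool, entity, duration, on_complete = NULL) {
  stopifnot(duration > 0)
  if (is.null(sim$handlers[["release"]])) {
    on_event(sim, "release", function(sim, ev) {
      pl <- ev$payload
      p <- pl$pool
      p$in_service <- p$in_service - 1L
      p$busy_time <- p$busy_time + pl$duration
      if (!is.null(pl$on_complete)) pl$on_complete(sim, pl$entity)
      # start next queued request, FIFO
      if (length(p$queue) > 0L && p$in_service < p$capacity) {
        req <- p$queue[[1L]]
        p$queue <- p$queue[-1L]
        p$waits[length(p$waits) + 1L] <- sim$clock - req$t_request
        p$in_service <- p$in_service + 1L
        schedule(sim, sim$clock + req$duration, "release",
                 payload = list(pool = p, duration = req$duration,
                                entity = req$entity,
                                on_complete = req$on_complete),
                 priority = -1L)
      }
    })
  }
  if (pool$in_service < pool$capacity) {
    pool$in_service <- pool$in_service + 1L
    pool$waits[length(pool$waits) + 1L] <- 0
    schedule(sim, sim$clock + duration, "release",
             payload = list(pool = pool, duration = duration, entity = entity,
                            on_complete = on_complete),
             priority = -1L)
  } else {
    pool$queue[[length(pool$queue) + 1L]] <-
      list(entity = entity, duration = duration, t_request = sim$clock,
           on_complete = on_complete)
  }
  invisible(TRUE)
}

#' Accrue open time on a pool
#'
#' @param pool A pool.
#' @param minutes Minutes of availability to add (per server; total available
#'   minutes grow by `capacity * minutes`).
#' @return The pool, invisibly.
#' @export
pool_open <- function(pool, minutes) {
  pool$open_time <- pool$open_time + minutes
  invisible(pool)
}

#' Accrue busy time on a pool directly
#'
#' Book-ahead accounting used by the clinic booking model, where capacity is
#' enforced when appointments are booked into sessions rather than by
#' minute-level queueing.
#'
#' @param pool A pool.
#' @param minutes Entity-minutes of service to add.
#' @return The pool, invisibly.
#' @export
pool_occupy <- function(pool, minutes) {
  pool$busy_time <- pool$busy_time + minutes
  invisible(pool)
}

#' Pool utilisation
#'
#' Utilisation = busy time / (capacity x open time), in `[0, 1]`.
#'
#' @param pool A pool.
#' @return Numeric scalar; `NA` if the pool has accumulated no open time.
#' @export
pool_utilisation <- function(pool) {
  denom <- pool$capacity * pool$open_time
  if (denom <= 0) return(NA_real_)
  pool$busy_time / denom
}

# ---- named random streams ---------------------------------------------------

#' Named reproducible random substreams
#'
#' Each named substream keeps its own saved RNG state, so that draws on one
#' stream are unaffected by how many draws other streams have consumed. This
#' enables common random numbers across scenario runs: scenarios that draw
#' the same sequence from the same substream see identical randomness.
#'
#' Substream seeds are derived deterministically from the master seed and the
#' stream's position in `names`.
#'
#' @param master_seed Integer master seed.
#' @param names Character vector of substream names.
#' @return An environment of class `rs_streams`.
#' @export
rng_streams <- function(master_seed,
                        names = c("init", "arrivals", "regimen", "routing",
                                  "durations", "dna", "scenario")) {
  st <- new.env(parent = emptyenv())
  st$states <- list()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  for (i in seq_along(names)) {
    # distinct 31-bit seed per substream
    s <- (as.numeric(master_seed) * 2654435761 + i * 40503) %% 2147483647
    set.seed(as.integer(s))
    st$states[[names[i]]] <- get(".Random.seed", globalenv())
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(st) <- c("rs_streams", "environment")
  st
}

#' Evaluate a random expression on a named substream
#'
#' Restores the substream's RNG state, evaluates `expr`, then saves the state
#' back, leaving the global RNG state as it was.
#'
#' @param streams Streams from [rng_streams()].
#' @param name Substream name.
#' @param expr Expression performing random draws.
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  if (is.null(streams$states[[name]])) stop("unknown substream '", name, "'")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  assign(".Random.seed", streams$states[[name]], globalenv())
  res <- force(expr)
  streams$states[[name]] <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  res
}
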
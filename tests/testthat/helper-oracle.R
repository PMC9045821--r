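# Independent oracles used across tests.
#
# tiny_hmm describes a miniature alignment model directly (per-slot variant
# Gaussians, admissible variant transitions with weights, transition
# probabilities, background Gaussian). The enumeration oracle computes the
# likelihood, posteriors and the best expected-accuracy path by explicit
# recursion over every admissible state sequence - no shared code with the
# package's dynamic programming.

tiny_hmm <- function(mu, sd, step_ok = NULL, skip_ok = NULL,
                     stay = 0.3, step = 0.55, skip = 0.1,
                     insert_open = 0.05, insert_extend = 0.1,
                     bg = c(100, 30)) {
  S <- length(mu)
  nv <- lengths(mu)
  if (is.null(step_ok) && S > 1)
    step_ok <- lapply(seq_len(S - 1), function(j)
      matrix(TRUE, nv[j], nv[j + 1]))
  if (is.null(skip_ok) && S > 2)
    skip_ok <- lapply(seq_len(S - 2), function(j)
      matrix(TRUE, nv[j], nv[j + 2]))
  list(S = S, nv = nv, mu = mu, sd = sd, step_ok = step_ok, skip_ok = skip_ok,
       trans = c(stay = stay, step = step, skip = skip,
                 io = insert_open, ie = insert_extend),
       bg = bg)
}

# all states as data.frame rows: kind (M/I), slot (1-based), variant
tiny_states <- function(h) {
  do.call(rbind, lapply(seq_len(h$S), function(j)
    do.call(rbind, lapply(seq_len(h$nv[j]), function(v)
      data.frame(kind = c("M", "I"), slot = j, variant = v)))))
}

tiny_emit <- function(h, state, x) {
  if (state$kind == "M") dnorm(x, h$mu[[state$slot]][state$variant], h$sd[[state$slot]][state$variant])
  else dnorm(x, h$bg[1], h$bg[2])
}

tiny_start_w <- function(h, state) {
  if (state$kind != "M") return(0)
  if (state$slot == 1) return(1 / h$nv[1])
  if (state$slot == 2 && h$S >= 2) return(h$trans["skip"] / h$nv[2])
  0
}

tiny_end_w <- function(h, state) {
  if (state$kind != "M") return(0)
  if (state$slot == h$S) return(1)
  if (state$slot == h$S - 1 && h$S >= 2) return(unname(h$trans["skip"]))
  0
}

tiny_trans_w <- function(h, from, to) {
  tr <- h$trans
  if (from$kind == "M") {
    if (to$kind == "M" && to$slot == from$slot && to$variant == from$variant)
      return(unname(tr["stay"]))
    if (to$kind == "I" && to$slot == from$slot && to$variant == from$variant)
      return(unname(tr["io"]))
    if (to$kind == "M" && to$slot == from$slot + 1) {
      ok <- h$step_ok[[from$slot]]
      if (!ok[from$variant, to$variant]) return(0)
      return(unname(tr["step"]) / sum(ok[from$variant, ]))
    }
    if (to$kind == "M" && to$slot == from$slot + 2) {
      ok <- h$skip_ok[[from$slot]]
      if (!ok[from$variant, to$variant]) return(0)
      return(unname(tr["skip"]) / sum(ok[from$variant, ]))
    }
    return(0)
  }
  # from Insert
  if (to$kind == "I" && to$slot == from$slot && to$variant == from$variant)
    return(unname(tr["ie"]))
  if (to$kind == "M" && to$slot == from$slot + 1) {
    ok <- h$step_ok[[from$slot]]
    if (!ok[from$variant, to$variant]) return(0)
    return((1 - unname(tr["ie"])) / sum(ok[from$variant, ]))
  }
  0
}

# enumerate all admissible paths (log space); returns list of
# (states indices, logprob)
tiny_paths <- function(h, events) {
  states <- tiny_states(h)
  E <- length(events)
  out <- list()
  lemit <- function(s, x) {
    if (s$kind == "M") dnorm(x, h$mu[[s$slot]][s$variant], h$sd[[s$slot]][s$variant], log = TRUE)
    else dnorm(x, h$bg[1], h$bg[2], log = TRUE)
  }
  recurse <- function(e, idx_path, lp) {
    s <- states[idx_path[e], ]
    lp <- lp + lemit(s, events[e])
    if (e == E) {
      w <- tiny_end_w(h, s)
      if (w > 0) out[[length(out) + 1]] <<- list(path = idx_path, logprob = lp + log(w))
      return()
    }
    for (nx in seq_len(nrow(states))) {
      w <- tiny_trans_w(h, s, states[nx, ])
      if (w > 0) recurse(e + 1, c(idx_path, nx), lp + log(w))
    }
  }
  for (st in seq_len(nrow(states))) {
    w <- tiny_start_w(h, states[st, ])
    if (w > 0) recurse(1, st, log(w))
  }
  out
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# oracle likelihood, posterior gamma over (event, slot, variant) Match
# states, and best expected-accuracy path score
tiny_oracle <- function(h, events) {
  paths <- tiny_paths(h, events)
  states <- tiny_states(h)
  lps <- vapply(paths, `[[`, 0, "logprob")
  ll <- logsumexp(lps)
  E <- length(events)
  gamma <- array(0, c(E, h$S, max(h$nv)))
  for (i in seq_along(paths)) {
    w <- exp(lps[i] - ll)
    for (e in seq_len(E)) {
      s <- states[paths[[i]]$path[e], ]
      if (s$kind == "M")
        gamma[e, s$slot, s$variant] <- gamma[e, s$slot, s$variant] + w
    }
  }
  mea <- -Inf
  for (p in paths) {
    sc <- 0
    for (e in seq_len(E)) {
      s <- states[p$path[e], ]
      if (s$kind == "M") sc <- sc + gamma[e, s$slot, s$variant]
    }
    if (sc > mea) mea <- sc
  }
  list(loglik = ll, gamma = gamma, mea_score = mea, n_paths = length(paths))
}

# run the package's DP on the same tiny model (direct call into the
# compiled kernel, mirroring slot_model's flattened layout)
tiny_align <- function(h, events, band_margin = 0L) {
  v_off <- c(0L, cumsum(h$nv))
  flat_edges <- function(ok_list, span) {
    off <- integer(h$S + 1)
    from <- to <- integer(0); lw <- numeric(0)
    for (j in seq_len(h$S)) {
      n <- 0L
      if (j + span <= h$S && !is.null(ok_list) && length(ok_list) >= j) {
        ok <- ok_list[[j]]
        for (u in seq_len(nrow(ok))) for (v in seq_len(ncol(ok))) if (ok[u, v]) {
          from <- c(from, u - 1L); to <- c(to, v - 1L)
          lw <- c(lw, -log(sum(ok[u, ])))
          n <- n + 1L
        }
      }
      off[j + 1] <- off[j] + n
    }
    list(off = off, from = from, to = to, lw = lw)
  }
  st <- flat_edges(h$step_ok, 1L)
  sk <- flat_edges(h$skip_ok, 2L)
  modprofiler:::hmm_align_cpp(events, v_off, unlist(h$mu), unlist(h$sd),
                              st$off, st$from, st$to, st$lw,
                              sk$off, sk$from, sk$to, sk$lw,
                              unname(h$trans), h$bg,
                              as.integer(band_margin), 1e-12, TRUE, TRUE)
}

random_tiny_instance <- function() {
  S <- sample(1:3, 1)
  nv <- sample(1:2, S, replace = TRUE)
  mu <- lapply(nv, function(n) runif(n, 80, 120))
  sd <- lapply(nv, function(n) runif(n, 0.5, 2))
  step_ok <- if (S > 1) lapply(seq_len(S - 1), function(j) {
    ok <- matrix(FALSE, nv[j], nv[j + 1])
    for (u in seq_len(nv[j])) ok[u, sample(seq_len(nv[j + 1]), sample(nv[j + 1], 1))] <- TRUE
    ok
  }) else NULL
  skip_ok <- if (S > 2) lapply(seq_len(S - 2), function(j) {
    ok <- matrix(FALSE, nv[j], nv[j + 2])
    for (u in seq_len(nv[j])) ok[u, sample(seq_len(nv[j + 2]), sample(nv[j + 2], 1))] <- TRUE
    ok
  }) else NULL
  h <- tiny_hmm(mu, sd, step_ok, skip_ok)
  E <- sample(1:4, 1)
  events <- runif(E, 75, 125)
  list(h = h, events = events)
}

# naive Ward agglomeration from raw points: at each step merge the pair
# minimizing the increase in within-cluster sum of squares; report heights
# sqrt(2 * delta ESS) (the ward.D2 scale on Euclidean input)
ward_oracle_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    m <- colMeans(x[rows, , drop = FALSE])
    sum(sweep(x[rows, , drop = FALSE], 2, m)^2)
  }
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (i < j) {
      d <- ess(c(clusters[[i]], clusters[[j]])) - ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, sqrt(2 * best))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small helper: a toy mod_sites data.frame with callable flags set manually
toy_sites <- function(contig, positions, canonical, mod_char = NULL,
                      callable = TRUE) {
  d <- data.frame(contig = contig, position = as.integer(positions),
                  canonical = canonical, mod_code = "Y", guide = "",
                  mod_char = mod_char %||% rep(NA_character_, length(positions)),
                  callable = callable, stringsAsFactors = FALSE)
  class(d) <- c("mod_sites", "data.frame")
  d
}
`%||%` <- function(a, b) if (is.null(a)) b else a
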
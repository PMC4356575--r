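# Exact brute-force oracle for a tiny village: enumerates every random
# branch of the daily dynamics (visit order, partner choice, each
# probabilistic rule cell) and accumulates the exact probability of
# every end-of-day configuration. Written independently of the package
# engine; transcribes the rule table a third time on purpose.

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

ev_branches <- function(kind, t, s, tm, maj, h, d) {
  same <- list(list(s = s, tm = tm, w = 1))
  if (kind == "police") {
    if (t %in% c(2, 3, 7) || (s == "C" && tm == 0)) return(same)
    if (t == 5 && maj != "C") return(same)
    if (h == 0) return(same)
    if (h == 1) return(list(list(s = "C", tm = d, w = 1)))
    return(list(list(s = "C", tm = d, w = h), list(s = s, tm = tm, w = 1 - h)))
  }
  if (kind == "offer") {
    if (t %in% c(1, 2, 3, 7) || (s == "C" && tm == 0)) return(same)
    if (t == 4) return(list(list(s = "C", tm = d, w = 1)))
    if (t == 5) {
      if (maj == "C") return(list(list(s = "C", tm = 0, w = 1)))
      return(same)
    }
    return(list(list(s = "C", tm = 0, w = 0.5), list(s = s, tm = tm, w = 0.5)))
  }
  if (kind == "tempt") {
    if (t %in% c(2, 3, 7) || s == "D") return(same)
    if (t %in% c(1, 4)) return(list(list(s = "D", tm = 0, w = 1)))
    if (t == 5) {
      if (maj == "D") return(list(list(s = "D", tm = 0, w = 1)))
      return(same)
    }
    return(list(list(s = "D", tm = 0, w = 0.5), list(s = s, tm = tm, w = 0.5)))
  }
  stop("unknown event")
}

# All outcomes of one meeting: list of (fs, ftm, ps, ptm, w).
enum_meeting <- function(ft, fs, ftm, pt, ps, ptm, maj, h, d) {
  out <- function(fs2, ftm2, pb) {
    lapply(pb, function(b)
      list(fs = fs2, ftm = ftm2, ps = b$s, ptm = b$tm, w = b$w))
  }
  same_p <- list(list(s = ps, tm = ptm, w = 1))
  if (ft == 1) {
    if (fs == "C" && ps == "D") return(out("D", 0, same_p))
    if (fs == "D" && ps == "C")
      return(out("D", 0, ev_branches("tempt", pt, ps, ptm, maj, h, d)))
    return(out(fs, ftm, same_p))
  }
  if (ft == 2) {
    if (ps != "D") return(out(fs, ftm, same_p))
    res <- list()
    for (ob in ev_branches("offer", pt, ps, ptm, maj, h, d)) {
      # no-police half
      res[[length(res) + 1L]] <- list(fs = fs, ftm = ftm, ps = ob$s,
                                      ptm = ob$tm, w = ob$w * 0.5)
      # police half, applied after the offer
      for (pb in ev_branches("police", pt, ob$s, ob$tm, maj, h, d))
        res[[length(res) + 1L]] <- list(fs = fs, ftm = ftm, ps = pb$s,
                                        ptm = pb$tm, w = ob$w * 0.5 * pb$w)
    }
    return(res)
  }
  if (ft == 3) {
    if (ps != "D") return(out(fs, ftm, same_p))
    res <- list(list(fs = fs, ftm = ftm, ps = ps, ptm = ptm, w = 0.5))
    for (ob in ev_branches("offer", pt, ps, ptm, maj, h, d))
      res[[length(res) + 1L]] <- list(fs = fs, ftm = ftm, ps = ob$s,
                                      ptm = ob$tm, w = 0.5 * ob$w)
    return(res)
  }
  if (ft == 4) {
    if (fs == "C" && ps == "D") return(out("D", 0, same_p))
    if (fs == "D" && ps == "C") return(out("C", d, same_p))
    return(out(fs, ftm, same_p))
  }
  if (ft == 5) {
    if (fs == "C" && ps == "D" && maj == "D") return(out("D", 0, same_p))
    if (fs == "D" && ps == "C" && maj == "C") return(out("C", 0, same_p))
    return(out(fs, ftm, same_p))
  }
  if (ft == 6) {
    if (fs == "C" && ps == "D")
      return(list(list(fs = "D", ftm = 0, ps = ps, ptm = ptm, w = 0.5),
                  list(fs = fs, ftm = ftm, ps = ps, ptm = ptm, w = 0.5)))
    if (fs == "D" && ps == "C")
      return(list(list(fs = "C", ftm = 0, ps = ps, ptm = ptm, w = 0.5),
                  list(fs = "D", ftm = 0, ps = ps, ptm = ptm, w = 0.5)))
    return(out(fs, ftm, same_p))
  }
  if (ft == 7) {
    if (ps == "D")
      return(out(fs, ftm, ev_branches("police", pt, ps, ptm, maj, h, d)))
    return(out(fs, ftm, same_p))
  }
  stop("unknown type")
}

# Exact distribution over end-of-day-(n_days) configurations.
# types: integer vector; returns named numeric (key = paste of states).
enumerate_village <- function(types, states, timers, h, d, n_days) {
  n <- length(types)
  acc <- new.env(parent = emptyenv())
  add <- function(key, w) {
    assign(key, w + mget(key, acc, ifnotfound = 0)[[1]], acc)
  }
  day <- function(st, tm, maj, w, k, perm, depth) {
    if (k > n) {
      for (i in seq_len(n)) {            # end-of-day timer expiry
        if (tm[i] > 0) { tm[i] <- tm[i] - 1; if (tm[i] == 0) st[i] <- "D" }
      }
      if (depth == n_days) {
        add(paste(st, collapse = ""), w)
      } else {
        frac <- mean(st == "C")
        maj2 <- if (frac > 0.5) "C" else if (frac < 0.5) "D" else "tie"
        start_day(st, tm, maj2, w, depth + 1L)
      }
      return(invisible())
    }
    f <- perm[k]
    for (q in setdiff(seq_len(n), f)) {
      wq <- w / (n - 1)
      for (b in enum_meeting(types[f], st[f], tm[f], types[q], st[q],
                             tm[q], maj, h, d)) {
        st2 <- st; tm2 <- tm
        st2[f] <- b$fs; tm2[f] <- b$ftm
        st2[q] <- b$ps; tm2[q] <- b$ptm
        day(st2, tm2, maj, wq * b$w, k + 1L, perm, depth)
      }
    }
  }
  start_day <- function(st, tm, maj, w, depth) {
    ps <- all_perms(seq_len(n))
    for (perm in ps) day(st, tm, maj, w / length(ps), 1L, perm, depth)
  }
  frac0 <- mean(states == "C")
  maj0 <- if (frac0 > 0.5) "C" else if (frac0 < 0.5) "D" else "tie"
  start_day(states, as.numeric(timers), maj0, 1, 1L)
  unlist(as.list(acc))
}
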
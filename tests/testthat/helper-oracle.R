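# Independent transcription of the behavioural rule table, kept separate
# from the package implementation on purpose: these tables were transcribed
# directly from the behavioural rule definitions and the package is
# checked against them cell by cell.
#
# oracle_meeting(): for a focal agent of a given type and state meeting
# a partner in a given state under a given majority signal, the exact
# probability that the focal ends the meeting cooperating, the timer it
# holds if it switched via a timed route, and the probabilities of each
# event directed at the partner.
#
# oracle_event(): the probability that a target of a given type/state
# ends up cooperating after one police / offer / tempt event.

oracle_meeting <- function(type, focal_state, partner_state, majority,
                           h, d) {
  p_police <- p_offer <- p_tempt <- 0
  # default: state unchanged
  p_c <- if (focal_state == "C") 1 else 0
  timer <- NA  # NA = unchanged / not a timed switch
  if (type == 1) {
    if (focal_state == "C" && partner_state == "D") p_c <- 0
    if (focal_state == "D" && partner_state == "C") p_tempt <- 1
  } else if (type == 2) {
    if (partner_state == "D") { p_offer <- 1; p_police <- 0.5 }
  } else if (type == 3) {
    if (partner_state == "D") p_offer <- 0.5
  } else if (type == 4) {
    if (focal_state == "C" && partner_state == "D") p_c <- 0
    if (focal_state == "D" && partner_state == "C") { p_c <- 1; timer <- d }
  } else if (type == 5) {
    if (focal_state == "C" && partner_state == "D")
      p_c <- if (majority == "D") 0 else 1
    if (focal_state == "D" && partner_state == "C")
      p_c <- if (majority == "C") 1 else 0
  } else if (type == 6) {
    if (focal_state == "C" && partner_state == "D") p_c <- 0.5
    if (focal_state == "D" && partner_state == "C") p_c <- 0.5
  } else if (type == 7) {
    if (partner_state == "D") p_police <- 1
  }
  list(p_c = p_c, timer = timer,
       p_police = p_police, p_offer = p_offer, p_tempt = p_tempt)
}

oracle_event <- function(kind, type, state, timer, majority, h, d) {
  p_c <- if (state == "C") 1 else 0
  untimed_c <- state == "C" && timer == 0
  if (kind == "police") {
    if (!(type %in% c(2, 3, 7)) && !untimed_c && state == "D") {
      if (type %in% c(1, 4, 6)) p_c <- h
      if (type == 5) p_c <- if (majority == "C") h else 0
    }
    # timed C target: renewal only, stays C (p_c already 1)
  } else if (kind == "offer") {
    if (!(type %in% c(1, 2, 3, 7)) && !untimed_c && state == "D") {
      if (type == 4) p_c <- 1
      if (type == 5) p_c <- if (majority == "C") 1 else 0
      if (type == 6) p_c <- 0.5
    }
  } else if (kind == "tempt") {
    if (!(type %in% c(2, 3, 7)) && state == "C") {
      if (type %in% c(1, 4)) p_c <- 0
      if (type == 5) p_c <- if (majority == "D") 0 else 1
      if (type == 6) p_c <- 0.5
    }
  }
  p_c
}

# Reachable (type, state, timer) combinations for cell enumeration.
# Types 2/3/7 only ever cooperate untimed; types 1 and 4 cooperate only
# inside a timed spell; types 5 and 6 can hold either kind of C.
oracle_focal_states <- function(type) {
  switch(as.character(type),
         "1" = list(c("D", 0), c("C", 3)),
         "4" = list(c("D", 0), c("C", 3)),
         "5" = list(c("D", 0), c("C", 0), c("C", 3)),
         "6" = list(c("D", 0), c("C", 0), c("C", 3)),
         list(c("C", 0)))
}

# Monte-Carlo estimate of a Bernoulli cell with its standard error.
mc_prob <- function(n, draw_fun) {
  hits <- sum(vapply(seq_len(n), function(i) draw_fun(), logical(1)))
  p <- hits / n
  list(p = p, se = sqrt(max(p * (1 - p), 1e-12) / n))
}

# Assert an estimated probability against the oracle value: exact for
# degenerate cells, within `k` standard errors otherwise.
expect_cell <- function(est, p_true, n, k = 3, label = "cell") {
  if (p_true %in% c(0, 1)) {
    expect_equal(est$p, p_true, info = label)
  } else {
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(est$p - p_true), k * se + 1e-12, label = label)
  }
}

# Exhaustive check of every meeting cell against the oracle at a given
# Monte-Carlo depth (probabilistic cells) and a small exact depth for
# deterministic cells.
check_meeting_cells <- function(params, n_draws) {
  for (type in 1:7) {
    for (fs in oracle_focal_states(type)) {
      for (ps in c("C", "D")) for (maj in c("C", "D", "tie")) {
        truth <- oracle_meeting(type, fs[1], ps, maj, params$h, params$d)
        probabilistic <- !(truth$p_c %in% c(0, 1)) ||
          !(truth$p_police %in% c(0, 1)) || !(truth$p_offer %in% c(0, 1))
        n <- if (probabilistic) n_draws else 25
        res <- vapply(seq_len(n), function(i) {
          out <- meeting_outcome(make_agent(type, fs[1], as.integer(fs[2])),
                                 ps, maj, params)
          c(coop = out$agent$state == "C",
            police = "police" %in% out$events,
            offer = "offer" %in% out$events,
            tempt = "tempt" %in% out$events)
        }, logical(4))
        lab <- sprintf("type %d %s(%s) meets %s, maj %s",
                       type, fs[1], fs[2], ps, maj)
        expect_cell(list(p = mean(res["coop", ])), truth$p_c, n, label = lab)
        expect_cell(list(p = mean(res["police", ])), truth$p_police, n,
                    label = paste(lab, "police"))
        expect_cell(list(p = mean(res["offer", ])), truth$p_offer, n,
                    label = paste(lab, "offer"))
        expect_cell(list(p = mean(res["tempt", ])), truth$p_tempt, n,
                    label = paste(lab, "tempt"))
      }
    }
  }
}

# Exhaustive check of every police/offer/tempt response cell.
check_event_cells <- function(params, n_draws) {
  impl <- list(police = apply_police, offer = apply_offer,
               tempt = apply_tempt)
  for (kind in names(impl)) {
    for (type in 1:7) {
      for (st in oracle_focal_states(type)) {
        for (maj in c("C", "D", "tie")) {
          p_true <- oracle_event(kind, type, st[1], as.numeric(st[2]),
                                 maj, params$h, params$d)
          n <- if (p_true %in% c(0, 1)) 25 else n_draws
          hits <- vapply(seq_len(n), function(i) {
            a <- impl[[kind]](make_agent(type, st[1], as.integer(st[2])),
                              maj, params)
            a$state == "C"
          }, logical(1))
          expect_cell(list(p = mean(hits)), p_true, n,
                      label = sprintf("%s type %d %s(%s) maj %s",
                                      kind, type, st[1], st[2], maj))
        }
      }
    }
  }
}
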
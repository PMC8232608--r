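# Independent oracles used across the suite.

# Brute-force cluster classifier: enumerates every opposite-strand break pair
# and every pair-of-pairs / pair-plus-extra-break combination explicitly.
oracle_classify <- function(position, strand, kind, rd = 10, window = rd) {
  br <- which(kind == "strand_break")
  if (length(br) == 0L) return("BD")
  p <- position[br]
  s <- strand[br]
  if (all(s == s[1L])) return(if (length(br) == 1L) "SSB" else "SSBp")
  pairs <- list()
  for (i in seq_along(br)) {
    for (j in seq_along(br)) {
      if (i < j && s[i] != s[j] && abs(p[i] - p[j]) < rd)
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) == 0L) return("SSB2")
  if (length(pairs) >= 2L) {
    for (a in seq_along(pairs)) {
      for (b in seq_along(pairs)) {
        if (a < b && !any(pairs[[a]] %in% pairs[[b]])) {
          cross <- Inf
          for (x in pairs[[a]]) for (y in pairs[[b]])
            cross <- min(cross, abs(p[x] - p[y]))
          if (cross < window) return("DSBpp")
        }
      }
    }
  }
  for (pr in pairs) {
    for (o in setdiff(seq_along(br), pr)) {
      if (min(abs(p[o] - p[pr[1L]]), abs(p[o] - p[pr[2L]])) < rd)
        return("DSBp")
    }
  }
  "DSB"
}

# Exact enumeration of the repair sampler's decision tree for one cluster:
# weighs the two strand-block processing orders and multiplies the per-lesion
# mutation branches analytically.
oracle_repair_probs <- function(cluster, params = repair_sim_parameters(),
                                pathway = "LP_BER") {
  patch_window <- c(SP_BER = 1, LP_BER = 8, SP_BER_NER = 30, LP_BER_NER = 30)
  uses_ner <- pathway %in% c("SP_BER_NER", "LP_BER_NER")
  inhib <- params$inhibition_distance + if (uses_ner) params$ner_span else 0
  patch <- patch_window[[pathway]]
  perr <- if (pathway == "SP_BER") params$polymerase_error_sp
          else params$polymerase_error_lp_ner
  pos <- cluster$position
  strand <- cluster$strand
  kind <- cluster$kind
  n <- length(pos)
  is_brk <- kind == "strand_break"
  both <- any(strand == 1L) && any(strand == 2L)
  orders <- if (both) {
    list(list(w = params$first_strand_choice_prob,
              ord = order(is_brk, strand != 1L, pos)),
         list(w = 1 - params$first_strand_choice_prob,
              ord = order(is_brk, strand != 2L, pos)))
  } else {
    list(list(w = 1, ord = order(is_brk, strand != strand[1L], pos)))
  }
  probs <- c(correct = 0, mutation = 0, enzymatic_dsb = 0)
  for (o in orders) {
    unrep <- rep(TRUE, n)
    p_no_mut <- 1
    dsb <- FALSE
    for (idx in o$ord) {
      po <- pos[idx]
      st <- strand[idx]
      opp <- strand != st & unrep
      if (kind[idx] != "strand_break" &&
          any(opp & kind == "strand_break" & abs(pos - po) <= inhib)) {
        dsb <- TRUE
        break
      }
      tmpl <- which(opp & kind != "strand_break" & abs(pos - po) < patch)
      if (length(tmpl)) {
        j <- tmpl[which.min(abs(pos[tmpl] - po))]
        pm <- if (kind[j] == "abasic_site")
          params$misinsertion_opposite_lost_base
        else params$misinsertion_opposite_damaged_base
        p_no_mut <- p_no_mut * (1 - pm)
      } else {
        p_no_mut <- p_no_mut * (1 - perr)
      }
      unrep[idx] <- FALSE
    }
    if (dsb) {
      probs["enzymatic_dsb"] <- probs["enzymatic_dsb"] + o$w
    } else {
      probs["correct"] <- probs["correct"] + o$w * p_no_mut
      probs["mutation"] <- probs["mutation"] + o$w * (1 - p_no_mut)
    }
  }
  probs
}

# Numeric isoeffect oracle: solve the reference dose matching the test
# radiation's LQ effect by root bracketing, then form the dose ratio.
oracle_rbe_survival <- function(ref, test, dose) {
  eff <- test$alpha * dose + test$beta * dose^2
  f <- function(D) ref$alpha * D + ref$beta * D^2 - eff
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = 1e-13)$root / dose
}

# Exact central binomial acceptance interval at the two-sided 3-sigma level
# (alpha = 0.0027); handles degenerate p = 0 or 1 exactly. For p > 0.5 the
# quantiles are computed on the complement: qbinom loses its lower tail when
# p is within ~1e-5 of 1.
binom_band <- function(n, p) {
  if (p > 0.5) {
    q <- 1 - p
    c(lo = n - qbinom(0.99865, n, q), hi = n - qbinom(0.00135, n, q))
  } else {
    c(lo = qbinom(0.00135, n, p), hi = qbinom(0.99865, n, p))
  }
}

# random cluster generator for property tests
random_cluster <- function(n_lesions, span = 30, origin = 100) {
  damage_cluster(
    position = origin + sample.int(span, n_lesions, replace = TRUE) - 1L,
    strand = sample(c(1L, 2L), n_lesions, replace = TRUE),
    kind = sample(lesion_kinds(), n_lesions, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
  )
}

# one unit in the last digit of a value printed at 3 significant figures
ulp3 <- function(x) 10^(floor(log10(abs(x))) - 2)
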
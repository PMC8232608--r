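# Enzymatic-DSB conversion and a simplified per-cluster excision-repair
# outcome sampler. Non-DSB clusters handled by base- or nucleotide-excision
# repair can be converted into double-strand breaks when the repair incision
# lands opposite an existing break ("enzymatic DSB").
#
# Two modes are supported. Table mode uses the packaged per-pathway outcome
# probabilities (authoritative for pipeline reproduction). Simulation mode
# samples per-cluster outcomes from an explicit decision tree parameterised by
# the published excision-repair simulation inputs (inhibition distance 8 bp,
# strand choice 0.5, polymerase errors 1e-4/1e-6, misinsertion 0.75).

.pathways <- c("SP_BER", "LP_BER", "SP_BER_NER", "LP_BER_NER")
.repair_outcomes <- c("correct", "mutation", "enzymatic_dsb")
# resynthesis patch per pathway (bp): short-patch BER replaces a single
# nucleotide, long-patch BER ~2-8, NER excises a ~24-32 nt oligo
.patch_window <- c(SP_BER = 1, LP_BER = 8, SP_BER_NER = 30, LP_BER_NER = 30)
.uses_ner <- c(SP_BER = FALSE, LP_BER = FALSE, SP_BER_NER = TRUE,
               LP_BER_NER = TRUE)

#' Repair pathways and outcomes
#'
#' @return `repair_pathways()`: the four excision-repair scenarios
#'   (short-patch BER, long-patch BER, and each combined with NER).
#'   `repair_outcome_labels()`: the three per-cluster outcomes.
#' @export
repair_pathways <- function() .pathways

#' @rdname repair_pathways
#' @export
repair_outcome_labels <- function() .repair_outcomes

#' Parameters of the excision-repair outcome sampler
#'
#' Defaults are the published simulation inputs: inhibition distance 8 base
#' pairs; probability 0.5 of starting repair on the first strand; polymerase
#' error 1e-4 for short-patch BER and 1e-6 for long-patch BER and NER;
#' misinsertion probability 0.75 opposite a damaged or lost base. `ner_span`
#' extends the incision reach of the NER pathways (the dual incisions flank
#' the excised oligonucleotide), an emulator choice documented in the methods
#' vignette.
#'
#' @param inhibition_distance Maximum distance (bp, inclusive) between a
#'   repair incision and an unrepaired break on the opposite strand that
#'   produces an enzymatic DSB; >= 1.
#' @param first_strand_choice_prob Probability of processing strand 1 first
#'   when both strands carry damage.
#' @param polymerase_error_sp,polymerase_error_lp_ner Resynthesis error
#'   probabilities per repaired lesion.
#' @param misinsertion_opposite_damaged_base,misinsertion_opposite_lost_base
#'   Misinsertion probabilities when the template opposite the patch carries a
#'   damaged base / an abasic site.
#' @param ner_span Extra incision reach (bp) for NER pathways.
#' @return A `repair_sim_parameters` object (list).
#' @export
repair_sim_parameters <- function(inhibition_distance = 8,
                                  first_strand_choice_prob = 0.5,
                                  polymerase_error_sp = 1e-4,
                                  polymerase_error_lp_ner = 1e-6,
                                  misinsertion_opposite_damaged_base = 0.75,
                                  misinsertion_opposite_lost_base = 0.75,
                                  ner_span = 20) {
  probs <- c(first_strand_choice_prob, polymerase_error_sp,
             polymerase_error_lp_ner, misinsertion_opposite_damaged_base,
             misinsertion_opposite_lost_base)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (inhibition_distance < 1)
    stop("'inhibition_distance' must be >= 1", call. = FALSE)
  if (ner_span < 0)
    stop("'ner_span' must be >= 0", call. = FALSE)
  structure(
    list(inhibition_distance = inhibition_distance,
         first_strand_choice_prob = first_strand_choice_prob,
         polymerase_error_sp = polymerase_error_sp,
         polymerase_error_lp_ner = polymerase_error_lp_ner,
         misinsertion_opposite_damaged_base =
           misinsertion_opposite_damaged_base,
         misinsertion_opposite_lost_base = misinsertion_opposite_lost_base,
         ner_span = ner_span),
    class = "repair_sim_parameters"
  )
}

# precompute scalar knobs for one (params, pathway) combination
.repair_knobs <- function(params, pathway) {
  pathway <- match.arg(pathway, .pathways)
  list(
    inhib = params$inhibition_distance +
      if (.uses_ner[[pathway]]) params$ner_span else 0,
    patch = .patch_window[[pathway]],
    q = params$first_strand_choice_prob,
    perr = if (pathway == "SP_BER") params$polymerase_error_sp
           else params$polymerase_error_lp_ner,
    mis_damaged = params$misinsertion_opposite_damaged_base,
    mis_lost = params$misinsertion_opposite_lost_base
  )
}

# One repair pass over a prepared cluster. kind codes: 1 break, 2 base
# damage, 3 abasic. ord1/ord2 are the two strand-block processing orders
# (ord2 NULL when only one strand carries damage). Draws exactly
# length(pos) + 1 uniforms regardless of the outcome so that runs with
# different inhibition distances stay pathwise aligned at a fixed seed.
# Returns 1 correct, 2 mutation, 3 enzymatic dsb.
.repair_once <- function(pos, strand, kindc, ord1, ord2, k) {
  n <- length(pos)
  u <- runif(n + 1L)
  ord <- if (is.null(ord2) || u[1L] < k$q) ord1 else ord2
  unrep <- rep.int(TRUE, n)
  mutated <- FALSE
  step <- 1L
  for (idx in ord) {
    step <- step + 1L
    po <- pos[idx]
    st <- strand[idx]
    opp <- strand != st & unrep
    if (kindc[idx] != 1L) {
      # excision of a base-class lesion incises the backbone: enzymatic DSB
      # if an unrepaired break sits on the opposite strand within reach
      if (any(opp & kindc == 1L & abs(pos - po) <= k$inhib)) return(3L)
    }
    # resynthesis across the patch
    tmpl <- which(opp & kindc != 1L & abs(pos - po) < k$patch)
    if (length(tmpl)) {
      j <- tmpl[which.min(abs(pos[tmpl] - po))]
      pm <- if (kindc[j] == 3L) k$mis_lost else k$mis_damaged
      if (u[step] < pm) mutated <- TRUE
    } else if (u[step] < k$perr) {
      mutated <- TRUE
    }
    unrep[idx] <- FALSE
  }
  if (mutated) 2L else 1L
}

.kind_code <- function(kind) match(kind, .lesion_kinds)

# Base-class lesions are excised before strand breaks are ligated
# (glycosylase/endonuclease action precedes the final ligation step of the
# pathway), so breaks sort after base lesions in the processing order; within
# each class, lesions on the chosen first strand come first, in position
# order.
.prepare_cluster <- function(cl) {
  kindc <- .kind_code(cl$kind)
  is_brk <- kindc == 1L
  both <- any(cl$strand == 1L) && any(cl$strand == 2L)
  list(pos = cl$position, strand = cl$strand, kindc = kindc,
       ord1 = order(is_brk, cl$strand != 1L, cl$position),
       ord2 = if (both) order(is_brk, cl$strand != 2L, cl$position))
}

#' Sample the repair outcome of one non-DSB cluster
#'
#' Lesions are processed one at a time: base-class lesions are excised before
#' pre-existing strand breaks are ligated, and within each class the starting
#' strand is chosen with `first_strand_choice_prob` when both strands carry
#' damage, each strand's lesions in position order. Excising a base-class
#' lesion incises the backbone; if an unrepaired break lies on the opposite
#' strand within the inhibition distance the cluster is converted into an
#' enzymatic DSB. Otherwise resynthesis commits a mutation with the pathway's
#' polymerase error probability, or with the misinsertion probability when the
#' template opposite the patch carries an unrepaired damaged or lost base.
#' Deterministic for a fixed seed.
#'
#' @param cluster A non-DSB-class [damage_cluster()]; DSB-class clusters are
#'   rejected (they are not excision-repair substrates).
#' @param params A [repair_sim_parameters()].
#' @param pathway One of [repair_pathways()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return One of `"correct"`, `"mutation"`, `"enzymatic_dsb"`.
#' @examples
#' cl <- damage_cluster(c(100, 103), strand = c(1, 2),
#'                      kind = c("strand_break", "abasic_site"))
#' simulate_repair(cl, repair_sim_parameters(), "LP_BER", seed = 1)
#' @export
simulate_repair <- function(cluster, params = repair_sim_parameters(),
                            pathway = "LP_BER", seed = NULL) {
  cluster <- as_damage_cluster(cluster)
  if (is_dsb_class(classify_cluster(cluster)))
    stop("DSB-class clusters are not excision-repair substrates",
         call. = FALSE)
  k <- .repair_knobs(params, pathway)
  pc <- .prepare_cluster(cluster)
  run <- function() .repair_once(pc$pos, pc$strand, pc$kindc, pc$ord1,
                                 pc$ord2, k)
  code <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  .repair_outcomes[code]
}

#' Monte Carlo repair-outcome probabilities over a cluster ensemble
#'
#' Runs [simulate_repair()] `n_reps` times over every cluster and returns the
#' outcome frequencies (counts normalised, so the three probabilities sum to
#' one exactly).
#'
#' @param clusters Non-empty list of non-DSB-class [damage_cluster()] objects.
#' @param params A [repair_sim_parameters()].
#' @param pathway One of [repair_pathways()].
#' @param n_reps Repeats per cluster (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `repair_outcome_probs` object: list with `pathway`, `p_correct`,
#'   `p_mutation`, `p_dsb` and the sample size `n`.
#' @export
outcome_probabilities <- function(clusters, params = repair_sim_parameters(),
                                  pathway = "LP_BER", n_reps = 1L,
                                  seed = NULL) {
  if (length(clusters) == 0L)
    stop("'clusters' must be a non-empty list", call. = FALSE)
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  k <- .repair_knobs(params, pathway)
  prepared <- lapply(clusters, function(cl) {
    cl <- as_damage_cluster(cl)
    if (is_dsb_class(classify_cluster(cl)))
      stop("DSB-class clusters are not excision-repair substrates",
           call. = FALSE)
    .prepare_cluster(cl)
  })
  run <- function() {
    counts <- integer(3L)
    for (cl in prepared) {
      for (r in seq_len(n_reps)) {
        code <- .repair_once(cl$pos, cl$strand, cl$kindc, cl$ord1, cl$ord2, k)
        counts[code] <- counts[code] + 1L
      }
    }
    counts
  }
  counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  n <- sum(counts)
  structure(
    list(pathway = pathway,
         p_correct = counts[1L] / n,
         p_mutation = counts[2L] / n,
         p_dsb = counts[3L] / n,
         n = n),
    class = "repair_outcome_probs"
  )
}

#' @export
print.repair_outcome_probs <- function(x, ...) {
  cat("<repair_outcome_probs> ", x$pathway, " (n = ", x$n, ")\n",
      "  correct ", signif(x$p_correct, 4),
      "  mutation ", signif(x$p_mutation, 4),
      "  enzymatic DSB ", signif(x$p_dsb, 4), "\n", sep = "")
  invisible(x)
}

#' Enzymatic-DSB yield from multiplicity-resolved conversion
#'
#' The yield of DSBs created during excision repair of non-DSB clusters:
#' \deqn{\mathrm{DSB} = \sum_i p_i Y_i}
#' where \eqn{Y_i} is the yield of non-DSB clusters of lesion multiplicity
#' \eqn{i} (per Gy per Gbp) and \eqn{p_i} the per-cluster conversion
#' probability. With a uniform \eqn{p_i = p} this reduces to \eqn{p} times the
#' total non-DSB yield.
#'
#' @param multiplicity_yields Named numeric vector, names = multiplicity
#'   \eqn{i}, values = \eqn{Y_i} >= 0 per Gy per Gbp.
#' @param conversion_probs Either a single probability applied uniformly, or a
#'   named numeric vector of \eqn{p_i} in \[0, 1\] covering every multiplicity
#'   present in `multiplicity_yields`.
#' @return Enzymatic-DSB yield per Gy per Gbp (0 for empty input).
#' @export
enzymatic_dsb_yield <- function(multiplicity_yields, conversion_probs) {
  if (length(multiplicity_yields) == 0L || length(conversion_probs) == 0L)
    return(0)
  if (any(multiplicity_yields < 0))
    stop("yields must be >= 0", call. = FALSE)
  if (any(conversion_probs < 0) || any(conversion_probs > 1))
    stop("conversion probabilities must be in [0, 1]", call. = FALSE)
  if (length(conversion_probs) == 1L && is.null(names(conversion_probs)))
    return(sum(conversion_probs * multiplicity_yields))
  keys <- names(multiplicity_yields)
  if (is.null(keys) || !all(keys %in% names(conversion_probs)))
    stop("'conversion_probs' must cover every multiplicity in ",
         "'multiplicity_yields'", call. = FALSE)
  sum(conversion_probs[keys] * multiplicity_yields)
}

#' Maximum enzymatic-DSB conversion of a spectrum
#'
#' Upper bound on the enzymatic-DSB yield under one pathway: every non-DSB
#' cluster is a conversion candidate, so the yield is
#' `(total damage - total DSB) * p_dsb`.
#'
#' @param spectrum A [damage_spectrum()] or named vector of category yields.
#' @param p_dsb Per-cluster DSB-formation probability of the pathway.
#' @return Yield per Gy per Gbp.
#' @export
max_dsb_conversion <- function(spectrum, p_dsb) {
  if (p_dsb < 0 || p_dsb > 1)
    stop("'p_dsb' must be in [0, 1]", call. = FALSE)
  tot <- aggregate_totals(spectrum)
  (tot[["total_damage"]] - tot[["total_DSB"]]) * p_dsb
}

#' Enzymatic share of the DSB induction yield
#'
#' @param enzymatic_yield Enzymatic-DSB yield per Gy per Gbp (>= 0).
#' @param dsb_induction_yield DSB induction yield per Gy per Gbp (> 0).
#' @return Percentage `100 * enzymatic_yield / dsb_induction_yield`.
#' @export
max_enzymatic_share <- function(enzymatic_yield, dsb_induction_yield) {
  if (any(dsb_induction_yield <= 0))
    stop("'dsb_induction_yield' must be > 0", call. = FALSE)
  100 * enzymatic_yield / dsb_induction_yield
}
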
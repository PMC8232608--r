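# Seedable Monte Carlo emulator of damage induction. Mirrors the two-step
# structure of damage-spectrum codes -- damage sites are scattered over the
# genome, then each site is resolved into individual lesions on a short duplex
# segment -- with simple, testable sub-distributions (Poisson cluster counts
# and multiplicities, uniform placement). It is an emulator, not a port of
# any published simulation code.

#' Configuration for the damage-induction emulator
#'
#' Defaults are calibrated to the packaged entrance-position (P1-like)
#' spectrum of a 62-MeV proton beam: `lesion_yield` 616 lesions per Gy per Gbp
#' (the P1 total damage yield), `break_fraction` 0.32 (giving the ~68% base
#' damage share), `cluster_density` 0.05 extra lesions per cluster, and oxygen
#' scaling factors 1.00/0.85/0.43 for 21/2/0.1% O2 derived from the ratios of
#' the packaged DSB yields. The scaling factors and density are calibration
#' choices of this emulator, not measured constants.
#'
#' @param lesion_yield Mean lesions per Gy per Gbp (>= 0).
#' @param break_fraction Probability that a lesion is a strand break, in
#'   \[0, 1\]; remaining lesions are split between base damage and abasic
#'   sites by `abasic_fraction`.
#' @param cluster_density Mean number of extra lesions per cluster beyond the
#'   first (Poisson; the LET surrogate), >= 0.
#' @param segment_length Length of the duplex window (base pairs) a cluster's
#'   lesions are placed in; default 25.
#' @param oxygen_scaling Named numeric map from oxygen percentage to a
#'   multiplicative yield factor in (0, 1].
#' @param abasic_fraction Share of non-break lesions that are abasic sites
#'   rather than damaged bases; default 0.2.
#' @param seed Default seed used by [generate_clusters()] when none is given.
#' @return A `generator_config` object (list).
#' @export
generator_config <- function(lesion_yield = 616,
                             break_fraction = 0.32,
                             cluster_density = 0.05,
                             segment_length = 25,
                             oxygen_scaling = c("21" = 1.00, "2" = 0.85,
                                                "0.1" = 0.43),
                             abasic_fraction = 0.2,
                             seed = NULL) {
  if (!is.numeric(lesion_yield) || lesion_yield < 0)
    stop("'lesion_yield' must be >= 0", call. = FALSE)
  if (break_fraction < 0 || break_fraction > 1)
    stop("'break_fraction' must be in [0, 1]", call. = FALSE)
  if (cluster_density < 0)
    stop("'cluster_density' must be >= 0", call. = FALSE)
  if (segment_length < 1)
    stop("'segment_length' must be >= 1", call. = FALSE)
  if (is.null(names(oxygen_scaling)) ||
      any(oxygen_scaling <= 0) || any(oxygen_scaling > 1))
    stop("'oxygen_scaling' must be a named map with factors in (0, 1]",
         call. = FALSE)
  if (abasic_fraction < 0 || abasic_fraction > 1)
    stop("'abasic_fraction' must be in [0, 1]", call. = FALSE)
  structure(
    list(lesion_yield = lesion_yield, break_fraction = break_fraction,
         cluster_density = cluster_density, segment_length = segment_length,
         oxygen_scaling = oxygen_scaling, abasic_fraction = abasic_fraction,
         seed = seed),
    class = "generator_config"
  )
}

#' Simulate damage clusters for one irradiation
#'
#' Draws a Poisson number of damage sites with mean
#' `lesion_yield / (1 + cluster_density) * dose * genome_size * oxygen factor`
#' (so the expected total lesion count is `lesion_yield * dose * genome_size *
#' factor`), then resolves each site into `1 + Poisson(cluster_density)`
#' lesions placed uniformly within a `segment_length` window, each lesion an
#' independent strand break with probability `break_fraction` on a uniformly
#' random strand. Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param dose Absorbed dose in Gy (>= 0).
#' @param genome_size Genome size in Gbp (> 0); 6 Gbp for a typical
#'   mammalian cell.
#' @param oxygen_pct Oxygen condition; must be a name of
#'   `config$oxygen_scaling`.
#' @param seed Integer seed; defaults to `config$seed`. `NULL` uses the
#'   current RNG state.
#' @return List of [damage_cluster()] objects (empty at dose 0).
#' @export
generate_clusters <- function(config, dose, genome_size, oxygen_pct = 21,
                              seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("'dose' must be a single non-negative number (Gy)", call. = FALSE)
  if (!is.numeric(genome_size) || genome_size <= 0)
    stop("'genome_size' must be > 0 (Gbp)", call. = FALSE)
  key <- as.character(oxygen_pct)
  if (!key %in% names(config$oxygen_scaling))
    stop("no oxygen scaling factor configured for ", key, "% O2",
         call. = FALSE)
  run <- function() {
    factor <- config$oxygen_scaling[[key]]
    mean_clusters <- config$lesion_yield / (1 + config$cluster_density) *
      dose * genome_size * factor
    n <- rpois(1L, mean_clusters)
    if (n == 0L) return(list())
    genome_bp <- genome_size * 1e9
    starts <- floor(runif(n, 1, genome_bp - config$segment_length))
    sizes <- 1L + rpois(n, config$cluster_density)
    total <- sum(sizes)
    offsets <- sample.int(config$segment_length, total, replace = TRUE) - 1L
    breaks <- runif(total) < config$break_fraction
    abasic <- runif(total) < config$abasic_fraction
    strands <- sample(c(1L, 2L), total, replace = TRUE)
    kind <- ifelse(breaks, "strand_break",
                   ifelse(abasic, "abasic_site", "base_damage"))
    # positions are whole-valued doubles: genome coordinates can exceed the
    # integer range
    pos <- rep.int(starts, sizes) + offsets
    out <- vector("list", n)
    from <- cumsum(c(1L, sizes[-n]))
    to <- cumsum(sizes)
    for (i in seq_len(n)) {
      sel <- from[i]:to[i]
      ord <- order(pos[sel])
      out[[i]] <- structure(
        list(position = pos[sel][ord],
             strand = strands[sel][ord],
             kind = kind[sel][ord]),
        class = "damage_cluster"
      )
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Estimate a damage-yield spectrum from simulated clusters
#'
#' Classifies every cluster with [classify_cluster()] and converts category
#' counts to yields per Gy per Gbp. The multiplicity breakdown (lesions per
#' cluster) is recorded for downstream enzymatic-DSB conversion.
#'
#' @param clusters List of [damage_cluster()] objects.
#' @param dose Absorbed dose in Gy (> 0 unless `clusters` is empty).
#' @param genome_size Genome size in Gbp (> 0).
#' @param rule_distance Passed to [classify_cluster()].
#' @return A [damage_spectrum()].
#' @export
estimate_spectrum <- function(clusters, dose, genome_size,
                              rule_distance = 10) {
  if (length(clusters) > 0 && dose <= 0)
    stop("'dose' must be > 0 when clusters are present", call. = FALSE)
  if (genome_size <= 0)
    stop("'genome_size' must be > 0", call. = FALSE)
  denom <- if (dose > 0) dose * genome_size else 1
  if (length(clusters) == 0L) {
    return(damage_spectrum(setNames(numeric(7), .damage_categories)))
  }
  cats <- vapply(clusters, classify_cluster, "",
                 rule_distance = rule_distance)
  mult <- vapply(clusters, cluster_multiplicity, 0L)
  counts <- table(factor(cats, levels = .damage_categories))
  yields <- as.numeric(counts) / denom
  names(yields) <- .damage_categories
  mdf <- as.data.frame(table(category = cats, multiplicity = mult),
                       stringsAsFactors = FALSE)
  mdf <- mdf[mdf$Freq > 0, ]
  multiplicity_yields <- data.frame(
    category = mdf$category,
    multiplicity = as.integer(as.character(mdf$multiplicity)),
    yield = mdf$Freq / denom
  )
  damage_spectrum(yields, multiplicity_yields = multiplicity_yields)
}
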
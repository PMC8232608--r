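# Domain types and classifier for clustered DNA damage on a duplex segment.
#
# A damage cluster is a set of lesions (strand breaks, base damage, abasic
# sites) at 1-based base-pair coordinates on strands 1/2 of a linear duplex.
# Clusters are classified into the standard seven categories used in
# Monte Carlo damage-spectrum work: BD, SSB, SSB+ ("SSBp"), 2SSB ("SSB2"),
# DSB, DSB+ ("DSBp"), DSB++ ("DSBpp").

.damage_categories <- c("BD", "SSB", "SSBp", "SSB2", "DSB", "DSBp", "DSBpp")
.lesion_kinds <- c("strand_break", "base_damage", "abasic_site")
.dsb_class <- c("DSB", "DSBp", "DSBpp")

#' Damage category labels
#'
#' The seven classes used for clustered-damage bookkeeping, in fixed order:
#' isolated base damage (`BD`); simple single-strand break (`SSB`); two or
#' more breaks on the same strand (`SSBp`, i.e. SSB+); breaks on opposite
#' strands that are all too far apart to constitute a double-strand break
#' (`SSB2`, i.e. 2SSB); simple double-strand break (`DSB`: two breaks on
#' opposite strands separated by fewer than 10 base pairs); a DSB with
#' additional break(s) on a strand nearby (`DSBp`, i.e. DSB+); and more than
#' one DSB in close proximity (`DSBpp`, i.e. DSB++).
#'
#' @return Character vector of the seven category labels.
#' @seealso [classify_cluster()]
#' @export
damage_categories <- function() .damage_categories

#' Lesion kinds
#'
#' Constituent lesion types of a damage cluster: `strand_break` (a nick in the
#' sugar-phosphate backbone), `base_damage` (a chemically altered base, a
#' base-excision-repair substrate) and `abasic_site` (a lost base; treated as
#' base-class, non-break damage for classification).
#'
#' @return Character vector of the three lesion kinds.
#' @export
lesion_kinds <- function() .lesion_kinds

#' Construct a damage cluster
#'
#' A cluster is a non-empty set of lesions on a short duplex segment, stored
#' sorted by position. Strand labels 1/2 carry no orientation semantics;
#' coordinates are 1-based integers.
#'
#' @param position Integer base-pair coordinates (>= 1). Recycled against the
#'   longest argument.
#' @param strand Strand of each lesion, 1 or 2.
#' @param kind Lesion kind; see [lesion_kinds()].
#' @return An object of class `damage_cluster`: a list with integer vectors
#'   `position`, `strand` and character vector `kind`, sorted by position.
#' @examples
#' damage_cluster(c(100, 105), strand = c(1, 2))            # a simple DSB
#' damage_cluster(120, strand = 1, kind = "base_damage")    # isolated BD
#' @export
damage_cluster <- function(position, strand = 1L, kind = "strand_break") {
  n <- max(length(position), length(strand), length(kind))
  if (n == 0L || length(position) == 0L)
    stop("a damage cluster must contain at least one lesion", call. = FALSE)
  position <- rep_len(position, n)
  strand <- rep_len(strand, n)
  kind <- rep_len(kind, n)
  if (!is.numeric(position) || any(!is.finite(position)) ||
      any(position < 1) || any(position != floor(position)))
    stop("'position' must be integer base-pair coordinates >= 1", call. = FALSE)
  if (!all(strand %in% c(1, 2)))
    stop("'strand' must be 1 or 2", call. = FALSE)
  if (!all(kind %in% .lesion_kinds))
    stop("'kind' must be one of: ", paste(.lesion_kinds, collapse = ", "),
         call. = FALSE)
  ord <- order(position, strand)
  structure(
    list(position = as.integer(position)[ord],
         strand = as.integer(strand)[ord],
         kind = as.character(kind)[ord]),
    class = "damage_cluster"
  )
}

#' @export
print.damage_cluster <- function(x, ...) {
  cat("<damage_cluster> ", cluster_multiplicity(x), " lesion(s)\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.damage_cluster <- function(x, ...) {
  data.frame(position = x$position, strand = x$strand, kind = x$kind)
}

#' Number of lesions in a cluster
#'
#' @param cluster A [damage_cluster()].
#' @return Integer lesion count (the cluster multiplicity, usually written
#'   \eqn{i}).
#' @export
cluster_multiplicity <- function(cluster) length(cluster$position)

as_damage_cluster <- function(x) {
  if (inherits(x, "damage_cluster")) return(x)
  if (is.data.frame(x)) return(damage_cluster(x$position, x$strand, x$kind))
  if (is.list(x) && all(c("position", "strand", "kind") %in% names(x)))
    return(damage_cluster(x$position, x$strand, x$kind))
  stop("cannot interpret input as a damage cluster", call. = FALSE)
}

#' Classify a damage cluster into one of the seven categories
#'
#' Applies the standard proximity rules for clustered damage on duplex DNA:
#' a cluster with no strand breaks is base damage (`BD`); breaks confined to
#' one strand give `SSB` (one break) or `SSBp` (two or more); breaks on
#' opposite strands form a DSB only when separated by fewer than
#' `rule_distance` base pairs, otherwise the cluster is `SSB2`.  A DSB with at
#' least one additional break within `rule_distance` of either of its ends is
#' `DSBp`; two disjoint opposite-strand break pairs, each a DSB and lying
#' within `dsb_pair_window` of one another (nearest-break separation), are
#' `DSBpp`.
#'
#' @param cluster A [damage_cluster()] (or data frame with columns `position`,
#'   `strand`, `kind`).
#' @param rule_distance Maximum opposite-strand break separation (exclusive)
#'   that constitutes a DSB; default 10 base pairs. "Within 10 base pairs" is
#'   interpreted as separation strictly less than 10.
#' @param dsb_pair_window Window (exclusive, nearest-break separation) within
#'   which two disjoint DSBs count as a single `DSBpp` cluster. Defaults to
#'   `rule_distance`; the window between DSB centres is not used.
#' @return A single category label; see [damage_categories()].
#' @examples
#' classify_cluster(damage_cluster(c(100, 105), strand = c(1, 2)))   # "DSB"
#' classify_cluster(damage_cluster(c(100, 115), strand = c(1, 2)))   # "SSB2"
#' classify_cluster(damage_cluster(c(100, 104, 107), strand = c(1, 2, 1)))
#' # "DSBp"
#' @export
classify_cluster <- function(cluster, rule_distance = 10,
                             dsb_pair_window = rule_distance) {
  cluster <- as_damage_cluster(cluster)
  if (rule_distance < 1)
    stop("'rule_distance' must be >= 1", call. = FALSE)
  brk <- cluster$kind == "strand_break"
  if (!any(brk)) return("BD")
  bp <- cluster$position[brk]
  bs <- cluster$strand[brk]
  if (all(bs == bs[1L]))
    return(if (length(bp) == 1L) "SSB" else "SSBp")
  p1 <- bp[bs == 1L]
  p2 <- bp[bs == 2L]
  sep <- abs(outer(p1, p2, "-"))
  edge <- which(sep < rule_distance, arr.ind = TRUE)
  if (nrow(edge) == 0L) return("SSB2")
  # DSB++: two disjoint break pairs, each a DSB, within the pair window
  if (nrow(edge) >= 2L) {
    for (a in seq_len(nrow(edge) - 1L)) {
      for (b in seq.int(a + 1L, nrow(edge))) {
        if (edge[a, 1L] != edge[b, 1L] && edge[a, 2L] != edge[b, 2L]) {
          pa <- c(p1[edge[a, 1L]], p2[edge[a, 2L]])
          pb <- c(p1[edge[b, 1L]], p2[edge[b, 2L]])
          if (min(abs(outer(pa, pb, "-"))) < dsb_pair_window)
            return("DSBpp")
        }
      }
    }
  }
  # DSB+: some DSB pair has an extra break within rule_distance of either end
  for (a in seq_len(nrow(edge))) {
    pa <- c(p1[edge[a, 1L]], p2[edge[a, 2L]])
    used1 <- which(bs == 1L)[edge[a, 1L]]
    used2 <- which(bs == 2L)[edge[a, 2L]]
    others <- setdiff(seq_along(bp), c(used1, used2))
    for (o in others)
      if (min(abs(bp[o] - pa)) < rule_distance) return("DSBp")
  }
  "DSB"
}

#' Is a category DSB-class?
#'
#' @param category Category label(s) from [damage_categories()].
#' @return Logical; `TRUE` for `DSB`, `DSBp`, `DSBpp`.
#' @export
is_dsb_class <- function(category) category %in% .dsb_class

#' Construct a damage-yield spectrum
#'
#' Per-category damage yields (per Gy per Gbp) for one position/oxygen
#' condition, optionally with the yield broken down by cluster lesion
#' multiplicity.
#'
#' @param yields Named numeric vector of non-negative yields over all seven
#'   categories of [damage_categories()], per Gy per Gbp.
#' @param position Position label (e.g. `"P1"` or `"Co60"`).
#' @param oxygen_pct Oxygen concentration in percent.
#' @param multiplicity_yields Optional data frame with columns `category`,
#'   `multiplicity`, `yield` giving the per-multiplicity breakdown; for each
#'   category present the yields must sum to that category's total (relative
#'   tolerance 1e-9).
#' @return An object of class `damage_spectrum`.
#' @export
damage_spectrum <- function(yields, position = NA_character_,
                            oxygen_pct = NA_real_,
                            multiplicity_yields = NULL) {
  if (!all(.damage_categories %in% names(yields)))
    stop("'yields' must be named over all categories: ",
         paste(setdiff(.damage_categories, names(yields)), collapse = ", "),
         call. = FALSE)
  yields <- as.numeric(yields[.damage_categories])
  names(yields) <- .damage_categories
  if (any(!is.finite(yields)) || any(yields < 0))
    stop("yields must be finite and >= 0", call. = FALSE)
  if (!is.null(multiplicity_yields)) {
    stopifnot(all(c("category", "multiplicity", "yield") %in%
                    names(multiplicity_yields)))
    agg <- tapply(multiplicity_yields$yield, multiplicity_yields$category, sum)
    for (cat in names(agg)) {
      tot <- yields[[cat]]
      if (abs(agg[[cat]] - tot) > 1e-9 * max(tot, 1e-12))
        stop("multiplicity yields for ", cat,
             " do not sum to the category yield", call. = FALSE)
    }
  }
  structure(
    list(yields = yields, position = position, oxygen_pct = oxygen_pct,
         multiplicity_yields = multiplicity_yields),
    class = "damage_spectrum"
  )
}

#' @export
print.damage_spectrum <- function(x, ...) {
  cat("<damage_spectrum> position=", x$position,
      " oxygen=", x$oxygen_pct, "% O2 (per Gy per Gbp)\n", sep = "")
  print(signif(x$yields, 3))
  tot <- aggregate_totals(x)
  cat("total SSB ", signif(tot[["total_SSB"]], 3),
      ", total DSB ", signif(tot[["total_DSB"]], 3),
      ", total damage ", signif(tot[["total_damage"]], 3), "\n", sep = "")
  invisible(x)
}

#' Aggregate a spectrum into total SSB, total DSB and total damage
#'
#' Totals follow the usual convention for damage-yield tables:
#' total SSB = SSB + SSB+ + 2SSB; total DSB = DSB + DSB+ + DSB++;
#' total damage = BD + total SSB + total DSB.
#'
#' @param spectrum A [damage_spectrum()], or a named numeric vector of the
#'   seven category yields.
#' @return Named numeric vector `total_SSB`, `total_DSB`, `total_damage`
#'   (per Gy per Gbp, full precision; round to 3 significant figures to mirror
#'   published tables).
#' @export
aggregate_totals <- function(spectrum) {
  y <- if (inherits(spectrum, "damage_spectrum")) spectrum$yields else spectrum
  if (!all(.damage_categories %in% names(y)))
    stop("missing damage categories: ",
         paste(setdiff(.damage_categories, names(y)), collapse = ", "),
         call. = FALSE)
  y <- y[.damage_categories]
  c(total_SSB = unname(y[["SSB"]] + y[["SSBp"]] + y[["SSB2"]]),
    total_DSB = unname(y[["DSB"]] + y[["DSBp"]] + y[["DSBpp"]]),
    total_damage = unname(sum(y)))
}

#' Read and write damage-yield tables
#'
#' Tab-separated format with header
#' `position oxygen_pct BD SSB SSBp SSB2 DSB DSBp DSBpp`
#' (yields per Gy per Gbp). Extra columns are preserved on read.
#'
#' @param path File path.
#' @return `read_damage_yields()` returns a data frame; `write_damage_yields()`
#'   returns `path` invisibly.
#' @export
read_damage_yields <- function(path) {
  if (!file.exists(path))
    stop("damage-yield table not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE)
  need <- c("position", "oxygen_pct", .damage_categories)
  if (!all(need %in% names(df)))
    stop("malformed damage-yield table ", path, ": missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_damage_yields
#' @param df Data frame as returned by [read_damage_yields()].
#' @export
write_damage_yields <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write damage clusters as JSON
#'
#' Interchange format: a JSON list of objects `{position, strand, kind}` per
#' cluster.
#'
#' @param path File path.
#' @return `read_clusters_json()` returns a list of [damage_cluster()] objects.
#' @export
read_clusters_json <- function(path) {
  if (!file.exists(path))
    stop("cluster file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(raw)) raw <- list(raw)
  lapply(raw, function(df) damage_cluster(df$position, df$strand, df$kind))
}

#' @rdname read_clusters_json
#' @param clusters List of [damage_cluster()] objects.
#' @export
write_clusters_json <- function(clusters, path) {
  payload <- lapply(clusters, as.data.frame)
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
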
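#' Pigment freshness index
#'
#' Ratio of chlorophyll a to the sum of chl a and its degradation products
#' (pheopigments): 1 means undegraded algal pigment, 0 fully degraded.
#' Where both pigments are zero the index is undefined and returned as `NA`.
#'
#' @param chl_a,pheopigment non-negative concentrations (vectors recycle).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' freshness_index(c(5, 0, 2), c(0, 3, 2))
#' @export
freshness_index <- function(chl_a, pheopigment) {
  if (any(chl_a < 0, na.rm = TRUE) || any(pheopigment < 0, na.rm = TRUE))
    stop_invalid("pigment concentrations must be non-negative")
  total <- chl_a + pheopigment
  out <- chl_a / total
  out[total == 0] <- NA_real_
  out
}

check_gene_profile <- function(profile, genes) {
  missing <- setdiff(genes, names(profile))
  if (length(missing))
    stop_invalid("gene profile lacks columns: ", paste(missing, collapse = ", "))
  for (g in genes)
    if (any(profile[[g]] < 0, na.rm = TRUE) || any(is.nan(profile[[g]])))
      stop_invalid("gene copy numbers must be finite and non-negative: ", g)
  profile
}

#' Domain rRNA gene ratios
#'
#' Per-depth ratios of domain-level rRNA gene copy numbers: BAR
#' (Bacteria-to-Archaea, `bac16S / arc16S`), EAR (Eukarya-to-Archaea,
#' `euk18S / arc16S`) and EBR (Eukarya-to-Bacteria, `euk18S / bac16S`).
#' Ratios are computed on linear copy numbers (display on log10 axes is a
#' plotting choice); a zero denominator yields `NA` for that ratio only.
#'
#' @param profile data frame with columns `bac16S`, `arc16S`, `euk18S`
#'   (copies per g wet sediment) plus any identifier columns, which are
#'   carried through.
#' @return The identifier columns of `profile` with `BAR`, `EAR`, `EBR`
#'   appended.
#' @export
domain_ratios <- function(profile) {
  profile <- check_gene_profile(profile, c("bac16S", "arc16S", "euk18S"))
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- profile
  out$BAR <- safe_div(profile$bac16S, profile$arc16S)
  out$EAR <- safe_div(profile$euk18S, profile$arc16S)
  out$EBR <- safe_div(profile$euk18S, profile$bac16S)
  out
}

#' Functional gene fractions of the 16S pool
#'
#' Percentage of total 16S rRNA gene copies (`bac16S + arc16S`) contributed
#' by each functional gene (`dsrB`, `soxB`, `narG`, `amoA`).  A fraction
#' above 100% is biologically implausible and triggers a warning; zero total
#' 16S yields `NA`.
#'
#' @param profile data frame with columns `bac16S`, `arc16S` and the four
#'   functional genes.
#' @return `profile`'s identifier columns with `pct_dsrB`, `pct_soxB`,
#'   `pct_narG`, `pct_amoA` appended.
#' @export
functional_fractions <- function(profile) {
  genes <- c("dsrB", "soxB", "narG", "amoA")
  profile <- check_gene_profile(profile, c("bac16S", "arc16S", genes))
  total <- profile$bac16S + profile$arc16S
  out <- profile
  for (g in genes) {
    pct <- ifelse(total > 0, 100 * profile[[g]] / total, NA_real_)
    if (any(pct > 100, na.rm = TRUE))
      warning(g, " exceeds total 16S copies (fraction > 100%)", call. = FALSE)
    out[[paste0("pct_", g)]] <- pct
  }
  out
}

#' Assign sediment zones
#'
#' Depth zonation of the study: bioturbated sediments split into the
#' physically-and-biologically impacted layer (PBL, 0 to 12.5 cm), the
#' biologically impacted layer (BL, 12.5 to 25 cm, the main lugworm feeding
#' depth) and undisturbed layers (UL, below 25 cm); nonbioturbated sediments
#' split into the physically impacted layer (PL, 0 to 12.5 cm) and UL below.
#' Boundaries are half-open and lower-inclusive: a depth exactly at 12.5 or
#' 25 cm falls in the deeper zone.
#'
#' @param depth depth in cm (vector), `>= 0`.
#' @param treatment `"bioturbated"` or `"nonbioturbated"` (recycled).
#' @return Character vector of zone labels (`"PBL"`, `"BL"`, `"UL"`, `"PL"`).
#' @examples
#' assign_zone(c(5, 12.5, 30), "bioturbated")
#' @export
assign_zone <- function(depth, treatment) {
  if (any(!is.finite(depth)) || any(depth < 0))
    stop_invalid("`depth` must be finite and >= 0")
  n <- max(length(depth), length(treatment))
  depth <- rep_len(depth, n)
  treatment <- rep_len(treatment, n)
  bad <- !treatment %in% c("bioturbated", "nonbioturbated")
  if (any(bad))
    stop_invalid("unknown treatment: ", paste(unique(treatment[bad]),
                                              collapse = ", "))
  ifelse(treatment == "bioturbated",
         ifelse(depth < 12.5, "PBL", ifelse(depth < 25, "BL", "UL")),
         ifelse(depth < 12.5, "PL", "UL"))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of freedom
#' and a two-sided p-value, used throughout for comparisons between sediment
#' categories.  If both groups have zero variance and identical values the
#' exact-equality fast path returns `t = 0`, `p = 1`.
#'
#' @param group_a,group_b numeric vectors, each of length `>= 2`.
#' @return List with `t`, `df` and `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_invalid("each group needs at least 2 observations")
  if (any(!is.finite(group_a)) || any(!is.finite(group_b)))
    stop_invalid("groups must be finite")
  va <- var(group_a); vb <- var(group_b)
  if (va == 0 && vb == 0) {
    if (group_a[1] == group_b[1])
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
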
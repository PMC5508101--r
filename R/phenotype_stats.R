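#' Per-environment trait summary
#'
#' Mean, sample SD (n-1 denominator), range and coefficient of variation
#' (CV% = 100 * SD / mean, one decimal) of the trait, grouped by
#' environment.
#'
#' @param phenotypes Phenotype data frame with columns `env` and `dtf`
#'   (and optionally `role`; only `role == "ril"` rows are summarized when
#'   the column is present).
#' @return Data frame with one row per environment: `env`, `n`, `mean`,
#'   `sd`, `min`, `max`, `cv_percent`.
#' @export
summarize_trait <- function(phenotypes) {
  if ("role" %in% names(phenotypes))
    phenotypes <- phenotypes[phenotypes$role == "ril", , drop = FALSE]
  if (nrow(phenotypes) < 2) stop("need at least 2 observations")
  out <- do.call(rbind, lapply(split(phenotypes$dtf, phenotypes$env), function(x) {
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x),
               cv_percent = cv_percent(mean(x), stats::sd(x)))
  }))
  out <- cbind(env = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Coefficient of variation in percent
#'
#' @param mean Trait mean.
#' @param sd Trait standard deviation.
#' @return `100 * sd / mean`, rounded to one decimal.
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop("CV undefined for zero mean")
  round(100 * sd / mean, 1)
}

# balanced genotype x environment check; returns list(E, R) or errors
check_balanced <- function(ph) {
  tab <- table(ph$individual, ph$env)
  if (length(unique(as.vector(tab))) != 1L || any(tab == 0))
    stop("unbalanced genotype x environment design; analyse per environment")
  list(E = ncol(tab), R = unique(as.vector(tab)))
}

#' Broad-sense heritability from a genotype x environment trial
#'
#' Variance components by the expected-mean-squares method from a
#' genotype x environment ANOVA with replication:
#' sigma2_e = MS_error, sigma2_ge = (MS_GE - MS_error)/R,
#' sigma2_g = (MS_G - MS_GE)/(E R). Entry-mean heritability is
#' H2 = sigma2_g / (sigma2_g + sigma2_ge/E + sigma2_e/(E R)), in percent.
#' With a single environment the G x E term drops and
#' H2 = sigma2_g / (sigma2_g + sigma2_e/R).
#' Negative component estimates are truncated at zero and flagged.
#'
#' @param phenotypes Phenotype data frame (`individual`, `env`, `dtf`;
#'   `role == "ril"` rows are used when a `role` column is present).
#' @return List with `sigma2_g`, `sigma2_ge`, `sigma2_e` (days^2),
#'   `h2_percent`, `n_env`, `n_rep`, `truncated` (logical).
#' @export
broad_sense_heritability <- function(phenotypes) {
  if ("role" %in% names(phenotypes))
    phenotypes <- phenotypes[phenotypes$role == "ril", , drop = FALSE]
  ph <- phenotypes
  ph$individual <- factor(ph$individual)
  ph$env <- factor(ph$env)
  if (nlevels(ph$individual) < 2) stop("need >= 2 genotypes")
  bal <- check_balanced(ph)
  E <- bal$E; R <- bal$R
  if (E < 2 && R < 2) stop("need >= 2 environments or >= 2 replicates")
  truncated <- FALSE
  if (E >= 2) {
    if (R >= 2) {
      tab <- stats::anova(stats::lm(dtf ~ individual * env, data = ph))
      ms <- tab[["Mean Sq"]]
      names(ms) <- rownames(tab)
      ms_g <- ms[["individual"]]; ms_ge <- ms[["individual:env"]]
      ms_err <- ms[["Residuals"]]
      sigma2_e <- ms_err
      sigma2_ge <- (ms_ge - ms_err) / R
      sigma2_g <- (ms_g - ms_ge) / (E * R)
    } else {
      # one replicate: GE confounded with error
      tab <- stats::anova(stats::lm(dtf ~ individual + env, data = ph))
      ms <- tab[["Mean Sq"]]
      names(ms) <- rownames(tab)
      sigma2_e <- 0
      sigma2_ge <- ms[["Residuals"]]
      sigma2_g <- (ms[["individual"]] - ms[["Residuals"]]) / E
    }
  } else {
    tab <- stats::anova(stats::lm(dtf ~ individual, data = ph))
    ms <- tab[["Mean Sq"]]
    names(ms) <- rownames(tab)
    sigma2_e <- ms[["Residuals"]]
    sigma2_ge <- 0
    sigma2_g <- (ms[["individual"]] - ms[["Residuals"]]) / R
  }
  comps <- c(sigma2_g, sigma2_ge, sigma2_e)
  if (any(comps < 0)) {
    truncated <- TRUE
    comps <- pmax(comps, 0)
  }
  sigma2_g <- comps[1]; sigma2_ge <- comps[2]; sigma2_e <- comps[3]
  denom <- sigma2_g + sigma2_ge / E + sigma2_e / (E * R)
  h2 <- if (denom > 0) 100 * sigma2_g / denom else 0
  list(sigma2_g = sigma2_g, sigma2_ge = sigma2_ge, sigma2_e = sigma2_e,
       h2_percent = h2, n_env = E, n_rep = R, truncated = truncated)
}

#' Two-factor genotype x environment ANOVA
#'
#' Standard fixed-effects decomposition for a balanced replicated trial:
#' sums of squares for genotype (G), environment (E), their interaction and
#' the residual, additive to the total.
#'
#' @param phenotypes Phenotype data frame (`individual`, `env`, `dtf`).
#' @return The `anova` table of `lm(dtf ~ individual * env)` with rows
#'   G, E, G:E and Residuals.
#' @export
gxe_anova <- function(phenotypes) {
  if ("role" %in% names(phenotypes))
    phenotypes <- phenotypes[phenotypes$role == "ril", , drop = FALSE]
  ph <- phenotypes
  ph$individual <- factor(ph$individual)
  ph$env <- factor(ph$env)
  tab <- table(ph$individual, ph$env)
  if (any(tab == 0)) stop("missing genotype x environment cells")
  stats::anova(stats::lm(dtf ~ individual * env, data = ph))
}

#' Transgressive segregation counts
#'
#' Counts RIL individuals (per-individual trait means) falling below the
#' early parent's mean - 2 SD and above the late parent's mean + 2 SD;
#' segregation is flagged bi-directional when both tails are populated.
#'
#' @param phenotypes Phenotype data frame with a `role` column containing
#'   `ril`, `parent_early` and `parent_late` rows, or supply parental
#'   summaries explicitly.
#' @param parent_early,parent_late Optional lists `list(mean =, sd =)`
#'   overriding the parental rows.
#' @return List with `n_below_early`, `n_above_late`, `bidirectional`.
#' @export
transgressive_segregation <- function(phenotypes, parent_early = NULL,
                                      parent_late = NULL) {
  get_parent <- function(role) {
    x <- phenotypes$dtf[phenotypes$role == role]
    if (!length(x)) stop("no rows with role ", role)
    list(mean = mean(x), sd = stats::sd(x))
  }
  if (is.null(parent_early)) parent_early <- get_parent("parent_early")
  if (is.null(parent_late)) parent_late <- get_parent("parent_late")
  ril <- phenotypes[phenotypes$role == "ril", , drop = FALSE]
  means <- tapply(ril$dtf, ril$individual, mean)
  lo <- parent_early$mean - 2 * parent_early$sd
  hi <- parent_late$mean + 2 * parent_late$sd
  n_below <- sum(means < lo)
  n_above <- sum(means > hi)
  list(n_below_early = n_below, n_above_late = n_above,
       bidirectional = n_below > 0 && n_above > 0)
}
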
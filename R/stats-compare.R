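#' Species and sympatry-class statistical battery
#'
#' Between-group tests run on population means (one measurement per
#' population, avoiding pseudoreplication): Welch's unequal-variance t-test
#' for two-group contrasts, Kruskal-Wallis for the three sympatry classes,
#' Bartlett's test for the variance-reduction prediction, and ordinary least
#' squares for trait-trait relationships. Proportions are
#' arcsine-square-root transformed before testing. All p-values are
#' two-sided; no multiple-testing correction is applied across the trait
#' battery (the FDR adjustment lives in the spatial KDE comparisons only).
#'
#' @name stats_compare
#' @keywords internal
NULL

comparison_row <- function(test, trait, statistic, df, p, groups, ns,
                           transform = "none") {
  data.frame(test = test, trait = trait, statistic = statistic,
             df = df, p_value = p,
             groups = paste(groups, collapse = " vs "),
             n = paste(ns, collapse = ", "),
             transform = transform, stringsAsFactors = FALSE)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom (wraps
#' \code{stats::t.test}).
#'
#' @param a,b numeric vectors (>= 2 values each; at least one group with
#'   nonzero variance).
#' @param trait,groups labels carried into the result row.
#' @return One-row comparison data frame: \code{statistic} (t), \code{df}
#'   (fractional), \code{p_value}.
#' @export
welch_t_test <- function(a, b, trait = NA_character_,
                         groups = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("Welch t-test needs >= 2 values per group", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both groups have zero variance", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  comparison_row("welch_t", trait, unname(ht$statistic),
                 unname(ht$parameter), ht$p.value, groups,
                 c(length(a), length(b)))
}

#' Kruskal-Wallis rank sum test
#'
#' H statistic with tie correction, referred to chi-squared with k - 1
#' degrees of freedom (wraps \code{stats::kruskal.test}). Empty groups are
#' dropped with a warning.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param trait label carried into the result row.
#' @return One-row comparison data frame.
#' @export
kruskal_wallis <- function(groups, trait = NA_character_) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty group(s) dropped from Kruskal-Wallis test")
    groups <- groups[!empty]
  }
  if (length(groups) < 2L || sum(lengths(groups)) < 3L)
    stop("Kruskal-Wallis needs >= 2 non-empty groups, total n >= 3",
         call. = FALSE)
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    stop("all observations identical: tie correction undefined", call. = FALSE)
  ht <- stats::kruskal.test(groups)
  comparison_row("kruskal_wallis", trait, unname(ht$statistic),
                 unname(ht$parameter), ht$p.value,
                 names(groups) %||% paste0("g", seq_along(groups)),
                 lengths(groups))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bartlett's test of homogeneity of variances
#'
#' Bartlett's K-squared with the standard correction factor, referred to
#' chi-squared with k - 1 degrees of freedom (wraps
#' \code{stats::bartlett.test}).
#'
#' @param groups list of >= 2 numeric vectors with >= 2 values and positive
#'   variance each.
#' @param trait label carried into the result row.
#' @return One-row comparison data frame.
#' @export
bartlett_test <- function(groups, trait = NA_character_) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("Bartlett's test needs >= 2 groups of >= 2 values", call. = FALSE)
  if (any(vapply(groups, stats::var, 0) == 0))
    stop("zero within-group variance", call. = FALSE)
  ht <- stats::bartlett.test(groups)
  comparison_row("bartlett", trait, unname(ht$statistic),
                 unname(ht$parameter), ht$p.value,
                 names(groups) %||% paste0("g", seq_along(groups)),
                 lengths(groups))
}

#' Ordinary least squares regression of y on x
#'
#' Slope, intercept, adjusted R-squared, and the overall F test (wraps
#' \code{stats::lm}).
#'
#' @param x,y numeric vectors, \code{x} non-constant, n >= 3.
#' @return List with \code{slope}, \code{intercept}, \code{r2_adj},
#'   \code{F}, \code{df} (numerator, denominator), \code{p_value}, \code{n}.
#' @export
linear_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("regression needs >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2_adj = sm$adj.r.squared,
       F = unname(fstat[1L]),
       df = unname(fstat[2:3]),
       p_value = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                  lower.tail = FALSE)),
       n = length(x))
}

#' Arcsine square-root transform for proportions
#'
#' \code{asin(sqrt(p))} in radians, the standard variance-stabilizing
#' transform applied to coverage proportions before testing.
#'
#' @param p proportions in [0, 1].
#' @return Transformed values in [0, pi/2].
#' @export
arcsine_sqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Run the full trait comparison battery on population means
#'
#' For each trait (sensilla count, coverage proportion, density, mean
#' nearest-neighbor distance; coverage arcsine-transformed first) runs, where
#' group sizes permit:
#' \itemize{
#'   \item the two-species contrast (Welch t on population means),
#'   \item the three sympatry-class contrast within \emph{E. carunculatum}
#'     (Kruskal-Wallis),
#'   \item the sympatric vs locally allopatric contrast within
#'     \emph{E. anna} (Welch t),
#'   \item the sympatric vs allopatric variance contrast within
#'     \emph{E. carunculatum} (Bartlett).
#' }
#' Contrasts whose groups are too small are skipped and listed in the
#' \code{skipped} attribute. Class means and standard errors of the
#' population means are returned alongside.
#'
#' @param pop_means population-mean table from
#'   \code{\link{aggregate_populations}} (must carry \code{species} and
#'   \code{patry}).
#' @param species_pair the two species labels to contrast (defaults to the
#'   study's pair).
#' @return Data frame of comparison rows, with attributes
#'   \code{class_summaries} (mean, SEM, n per species x patry x trait) and
#'   \code{skipped}.
#' @export
run_comparison_battery <- function(pop_means,
                                   species_pair = c("E_anna",
                                                    "E_carunculatum")) {
  stopifnot(all(c("species", "patry") %in% names(pop_means)))
  traits <- c(sensilla_count = "none", coverage_proportion = "arcsine_sqrt",
              density = "none", mean_nnd = "none")
  rows <- list(); skipped <- character(0)
  summaries <- list()
  for (trait in names(traits)) {
    vals <- pop_means[[trait]]
    if (traits[[trait]] == "arcsine_sqrt") vals <- arcsine_sqrt(vals)
    ok <- !is.na(vals)
    df <- data.frame(value = vals[ok], species = pop_means$species[ok],
                     patry = pop_means$patry[ok], stringsAsFactors = FALSE)
    for (sp in unique(df$species)) for (cl in unique(df$patry)) {
      v <- df$value[df$species == sp & df$patry == cl]
      if (length(v))
        summaries[[length(summaries) + 1L]] <-
          data.frame(trait = trait, species = sp, patry = cl,
                     mean = mean(v), sem = if (length(v) > 1L) .sem(v) else NA,
                     n_populations = length(v), stringsAsFactors = FALSE)
    }
    try_add <- function(label, expr) {
      res <- tryCatch(expr, error = function(e) e)
      if (inherits(res, "error"))
        skipped <<- c(skipped, paste0(trait, "/", label, ": ",
                                      conditionMessage(res)))
      else rows[[length(rows) + 1L]] <<- res
    }
    a <- df$value[df$species == species_pair[1L]]
    b <- df$value[df$species == species_pair[2L]]
    try_add("species", welch_t_test(a, b, trait, species_pair))
    ec <- df[df$species == species_pair[2L], ]
    gr <- split(ec$value, factor(ec$patry, levels = PATRY_LEVELS))
    try_add("Ec_patry", kruskal_wallis(gr, trait))
    ea <- df[df$species == species_pair[1L], ]
    try_add("Ea_patry",
            welch_t_test(ea$value[ea$patry == "locally_allopatric"],
                         ea$value[ea$patry == "sympatric"], trait,
                         c("locally_allopatric", "sympatric")))
    try_add("Ec_variance",
            bartlett_test(list(sympatric = ec$value[ec$patry == "sympatric"],
                               allopatric = ec$value[ec$patry == "allopatric"]),
                          trait))
  }
  out <- do.call(rbind, rows)
  attr(out, "class_summaries") <- do.call(rbind, summaries)
  attr(out, "skipped") <- skipped
  out
}
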
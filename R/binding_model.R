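#' One-site competition signal
#'
#' The standard one-site competition model with Hill slope 1:
#' `S(c) = bottom + (top - bottom) / (1 + c / IC50)`. `top` is the
#' uninhibited signal (no competitor), `bottom` the fully inhibited signal,
#' and `IC50` the competitor concentration halving the specific signal.
#'
#' @param params List with `top`, `bottom`, `ic50_uM` (see
#'   [competition_params()]).
#' @param conc_uM Competitor concentration(s), uM, >= 0.
#' @return Model signal(s).
#' @export
competition_signal <- function(params, conc_uM) {
  stopifnot(all(conc_uM >= 0))
  params$bottom + (params$top - params$bottom) / (1 + conc_uM / params$ic50_uM)
}

#' Construct one-site competition model parameters
#'
#' @param top Uninhibited signal; must exceed `bottom`.
#' @param bottom Fully inhibited signal, >= 0.
#' @param ic50_uM Half-maximal inhibitory concentration, uM, > 0.
#' @return List of class `competition_params`.
#' @export
competition_params <- function(top, bottom, ic50_uM) {
  stopifnot(top > bottom, bottom >= 0, ic50_uM > 0)
  structure(list(top = top, bottom = bottom, ic50_uM = ic50_uM, hill = 1),
            class = "competition_params")
}

#' Simulate a dot-blot competition series
#'
#' Generates replicate signals at each competitor concentration as the
#' one-site model value plus Gaussian noise, clipped at zero (densitometry
#' signals cannot be negative). Fully reproducible given `seed`.
#'
#' @param params [competition_params()].
#' @param concentrations_uM Non-negative concentrations (>= 4 distinct values
#'   are required later for fitting).
#' @param n_reps Replicates per concentration (default 3).
#' @param noise_sd Gaussian noise standard deviation in signal units.
#' @param seed Integer seed (required).
#' @param label Assay label, e.g. `"FKBP51 x Hsp90b"`.
#' @return List of class `competition_assay`: `label`, `concentrations_uM`,
#'   `signals` (n_reps x n_conc matrix), `seed`, `true_params`.
#' @export
simulate_competition_assay <- function(params, concentrations_uM,
                                       n_reps = 3L, noise_sd = 0,
                                       seed, label = "") {
  if (length(concentrations_uM) == 0L) stop("empty concentration list")
  stopifnot(noise_sd >= 0, all(concentrations_uM >= 0))
  if (missing(seed)) stop("seed is required")
  mu <- competition_signal(params, concentrations_uM)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  sig <- matrix(rep(mu, each = n_reps), nrow = n_reps) +
    matrix(stats::rnorm(n_reps * length(mu), 0, noise_sd), nrow = n_reps)
  sig[sig < 0] <- 0
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  colnames(sig) <- as.character(concentrations_uM)
  structure(
    list(label = label, concentrations_uM = concentrations_uM,
         signals = sig, seed = as.integer(seed), true_params = params),
    class = "competition_assay"
  )
}

#' Write / read a competition assay as TSV
#'
#' Long format with columns `conc_uM`, `rep`, `signal`.
#'
#' @param assay A `competition_assay`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(assay, path) {
  long <- data.frame(
    conc_uM = rep(assay$concentrations_uM, each = nrow(assay$signals)),
    rep = rep(seq_len(nrow(assay$signals)), length(assay$concentrations_uM)),
    signal = as.vector(assay$signals)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_table
#' @param label Assay label attached on read.
#' @return For `read_assay_table`, a `competition_assay` (without
#'   `true_params`).
#' @export
read_assay_table <- function(path, label = "") {
  long <- utils::read.delim(path)
  concs <- sort(unique(long$conc_uM))
  reps <- sort(unique(long$rep))
  sig <- matrix(NA_real_, nrow = length(reps), ncol = length(concs),
                dimnames = list(NULL, as.character(concs)))
  for (i in seq_len(nrow(long))) {
    sig[match(long$rep[i], reps), match(long$conc_uM[i], concs)] <-
      long$signal[i]
  }
  structure(list(label = label, concentrations_uM = concs, signals = sig,
                 seed = NA_integer_, true_params = NULL),
            class = "competition_assay")
}

#' Fit the one-site competition model to an assay
#'
#' Least-squares fit of `(top, bottom, IC50)` with the Hill slope fixed at 1.
#' The IC50 is parameterized internally as log10(IC50) so the optimizer works
#' on the concentration scale the data span. Initialization: `top` = largest
#' per-concentration mean, `bottom` = smallest, IC50 = geometric midpoint of
#' the positive concentration range. Box constraints: `bottom >= 0`,
#' IC50 in `[min positive conc / 100, max conc * 100]`.
#'
#' @param assay A `competition_assay`.
#' @param fix_top,fix_bottom Optionally fix the plateau parameters at given
#'   values instead of floating them.
#' @return List of class `ic50_fit`: `params` (fitted `competition_params`),
#'   `se` (named standard errors), `rss`, `converged`, `n_points`,
#'   `message`.
#' @export
fit_ic50 <- function(assay, fix_top = NULL, fix_bottom = NULL) {
  conc <- rep(assay$concentrations_uM, each = nrow(assay$signals))
  y <- as.vector(assay$signals)
  keep <- !is.na(y)
  conc <- conc[keep]; y <- y[keep]
  if (length(unique(conc)) < 4L) {
    stop("need >= 4 distinct concentrations to fit")
  }
  means <- tapply(y, conc, mean)
  if (diff(range(means)) <= 1e-9 * max(abs(means), 1)) {
    stop("no transition: signal is flat across concentrations")
  }
  pos <- conc[conc > 0]
  lo_ic <- log10(min(pos) / 100)
  hi_ic <- log10(max(pos) * 100)
  start <- c(top = unname(max(means)), bottom = unname(min(means)),
             l10ic50 = (log10(min(pos)) + log10(max(pos))) / 2)
  free <- c(if (is.null(fix_top)) "top",
            if (is.null(fix_bottom)) "bottom", "l10ic50")
  full_par <- function(p) {
    c(top = if (is.null(fix_top)) p[["top"]] else fix_top,
      bottom = if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom,
      l10ic50 = p[["l10ic50"]])
  }
  resid_fn <- function(p) {
    pp <- full_par(p)
    y - (pp[["bottom"]] + (pp[["top"]] - pp[["bottom"]]) /
           (1 + conc / 10^pp[["l10ic50"]]))
  }
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start[free],
      lower = c(top = -Inf, bottom = 0, l10ic50 = lo_ic)[free],
      upper = c(top = Inf, bottom = Inf, l10ic50 = hi_ic)[free],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e
  )
  if (inherits(res, "error") || !(res$info %in% 1:4)) {
    msg <- if (inherits(res, "error")) conditionMessage(res) else res$message
    return(structure(list(params = NULL, se = NULL, rss = NA_real_,
                          converged = FALSE, n_points = length(y),
                          message = msg),
                     class = "ic50_fit"))
  }
  pp <- full_par(res$par)
  ic50_hat <- 10^pp[["l10ic50"]]
  dof <- max(1L, length(y) - length(free))
  se <- c(top = NA_real_, bottom = NA_real_, ic50_uM = NA_real_)
  covm <- tryCatch(res$deviance / dof * solve(res$hessian),
                   error = function(e) NULL)
  if (!is.null(covm)) {
    se_raw <- sqrt(pmax(diag(covm), 0))
    names(se_raw) <- free
    if ("top" %in% free) se[["top"]] <- se_raw[["top"]]
    if ("bottom" %in% free) se[["bottom"]] <- se_raw[["bottom"]]
    # delta method: d(10^x)/dx = ln(10) 10^x
    se[["ic50_uM"]] <- log(10) * ic50_hat * se_raw[["l10ic50"]]
  }
  structure(
    list(params = competition_params(pp[["top"]], pp[["bottom"]], ic50_hat),
         se = se, rss = res$deviance, converged = TRUE,
         n_points = length(y), message = "converged"),
    class = "ic50_fit"
  )
}

#' Equilibrium occupancy of a labeled ligand under competition
#'
#' Fraction of receptor bound by the labeled ligand in the presence of a
#' competitor, under the ligand-excess approximation (free concentrations ~
#' total concentrations): `occ = (L/KdL) / (1 + L/KdL + I/KdI)`. This algebra
#' quantifies hierarchical displacement: a competitor much weaker than the
#' labeled ligand barely reduces occupancy even at equal concentration.
#'
#' @param kd_labeled_uM,kd_competitor_uM Dissociation constants, uM, > 0.
#' @param conc_labeled_uM Labeled-ligand concentration, uM, > 0.
#' @param conc_competitor_uM Competitor concentration, uM, >= 0.
#' @return Occupied fraction in [0, 1).
#' @export
displacement_occupancy <- function(kd_labeled_uM, kd_competitor_uM,
                                   conc_labeled_uM, conc_competitor_uM) {
  stopifnot(kd_labeled_uM > 0, kd_competitor_uM > 0,
            conc_labeled_uM > 0, conc_competitor_uM >= 0)
  l <- conc_labeled_uM / kd_labeled_uM
  i <- conc_competitor_uM / kd_competitor_uM
  l / (1 + l + i)
}

#' Classify peptide affinities per dcTPR protein
#'
#' For each dcTPR protein with at least two fitted pairs, labels a pair
#' low-affinity when its IC50 is at least `fold_threshold` times the
#' per-protein minimum (and strictly above the minimum, so the best binder
#' and its ties are always high-affinity). dcTPR proteins with a single fit
#' get `unclassified`.
#'
#' @param fits data.frame with columns `dctpr`, `peptide`, `ic50_uM`.
#' @param fold_threshold Fold difference defining the low-affinity tier
#'   (default 10).
#' @return `fits` with added columns `min_ic50_uM`, `fold_vs_min`, `tier`.
#' @export
classify_affinity_tiers <- function(fits, fold_threshold = 10) {
  stopifnot(all(c("dctpr", "peptide", "ic50_uM") %in% names(fits)))
  out <- fits
  out$min_ic50_uM <- stats::ave(out$ic50_uM, out$dctpr, FUN = min)
  out$fold_vs_min <- out$ic50_uM / out$min_ic50_uM
  n_per <- stats::ave(out$ic50_uM, out$dctpr, FUN = length)
  out$tier <- ifelse(
    n_per < 2, "unclassified",
    ifelse(out$fold_vs_min >= fold_threshold & out$ic50_uM > out$min_ic50_uM,
           "low", "high"))
  out
}
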
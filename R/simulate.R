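#' Default simulation design for a two-study PFAS exposure experiment
#'
#' Describes the synthetic experiment the generator emulates: four compounds
#' with known true potencies, two independent studies with triplicate wells,
#' two-fold concentration grids up to 100 uM (33 uM for the most potent
#' compound), a shared decreasing curve shape, and lognormal well-to-well
#' noise with constant coefficient of variation on the natural scale. The
#' default true potencies \code{b = c(PFOA = 9.8, PFOS = 11.7, PFNA = 6.1,
#' PFHxS = 31.0)} uM with \code{c = 0.2}, \code{d = 1.5} and background 1
#' are test-fixture magnitudes for a realistic decreasing fold-change
#' endpoint, not claims about any real dataset.
#'
#' @param b Named vector of true potencies (uM), one per compound.
#' @param a Named vector of per-study backgrounds (fold change), or a single
#'   shared value; names define the study labels.
#' @param c True plateau ratio.
#' @param d True steepness.
#' @param cv Natural-scale coefficient of variation of well noise.
#' @param concentrations Named list of concentration grids (uM, including 0),
#'   one per compound; defaults to two-fold series up to 100 uM, except
#'   33 uM for the compound with the smallest \code{b}.
#' @param n_replicates Wells per group (default 3).
#' @param seed Integer seed; the design is fully deterministic given it.
#' @return An object of class \code{"sim_design"}.
#' @export
sim_design <- function(b = c(PFOA = 9.8, PFOS = 11.7, PFNA = 6.1,
                             PFHxS = 31.0),
                       a = c(S1 = 1, S2 = 1),
                       c = 0.2, d = 1.5, cv = 0.15,
                       concentrations = NULL,
                       n_replicates = 3L, seed = 1L) {
  stopifnot(!is.null(names(b)), all(b > 0), all(a > 0), c > 0, d > 0,
            cv >= 0, n_replicates >= 1L)
  if (is.null(names(a))) names(a) <- paste0("S", seq_along(a))
  if (is.null(concentrations)) {
    grid100 <- c(0, 100 / 2^(6:0))          # 0, 1.5625 ... 100 uM
    grid33 <- c(0, 33 / 2^(6:0))            # 0, 0.516 ... 33 uM
    most_potent <- names(b)[which.min(b)]
    concentrations <- lapply(names(b), function(cmp)
      if (cmp == most_potent) grid33 else grid100)
    names(concentrations) <- names(b)
  }
  stopifnot(setequal(names(concentrations), names(b)),
            all(vapply(concentrations, function(g) any(g == 0), logical(1))))
  structure(list(b = b, a = a, c = c, d = d, cv = cv,
                 concentrations = concentrations,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate a concentration-response summary table
#'
#' For each (compound, study, concentration) group, draws
#' \code{n_replicates} lognormal fold changes whose arithmetic mean equals
#' the exponential-model curve at the design's coefficient of variation
#' (log-scale sd \code{sqrt(log(1 + cv^2))}, log-scale mean shifted by half
#' that variance below the log curve value), then reports the arithmetic
#' mean, sample SD and n. Fully deterministic given the design's seed.
#'
#' @param design A [sim_design()].
#' @param endpoint Endpoint label for the resulting table.
#' @return A [summary_table()].
#' @export
simulate_summary_table <- function(design, endpoint = "RAG1") {
  stopifnot(inherits(design, "sim_design"))
  .with_seed(design$seed, {
    rows <- list()
    for (cmp in names(design$b)) {
      for (st in names(design$a)) {
        for (x in design$concentrations[[cmp]]) {
          m_true <- expo_response(x, design$a[[st]], design$b[[cmp]],
                                  design$c, design$d)
          draws <- .rlnorm_mean_cv(design$n_replicates, m_true, design$cv)
          rows[[length(rows) + 1L]] <- data.frame(
            compound = cmp, study = st, concentration = x,
            mean = mean(draws),
            sd = if (design$n_replicates > 1) stats::sd(draws) else 0,
            n = design$n_replicates, stringsAsFactors = FALSE)
        }
      }
    }
    summary_table(do.call(rbind, rows), endpoint = endpoint)
  })
}

# Lognormal draws with arithmetic mean m and coefficient of variation cv.
.rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s2 <- log1p(cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a raw qPCR experiment (wells, dilution series, plate design)
#'
#' Generates the inputs the quantification stage consumes: per-well Cq
#' measurements for a target and a reference gene, a five-point two-fold
#' standard-curve dilution series per gene, and the plate design mapping
#' samples to (compound, study, concentration). Each well's true target
#' quantity follows the design's exponential concentration-response curve
#' with lognormal noise at the design cv; the reference gene is constant at
#' \code{reference_level}. Cq values come from inverting the standard curve
#' (\code{cq = intercept + slope * log10(quantity)}) plus Gaussian
#' measurement noise. Running [quantify()], [summarize_to_table()] and
#' [fit_model()] on this output recovers the design parameters.
#'
#' @param design A [sim_design()].
#' @param curve_slope Standard-curve slope, cycles per log10 unit (< 0);
#'   default \code{-1/log10(2)}, i.e. 100\% amplification efficiency.
#' @param curve_intercept Standard-curve intercept, cycles (default 25).
#' @param reference_level Constant true quantity of the reference gene
#'   (default 1).
#' @param cq_noise_sd SD of Gaussian Cq measurement noise, cycles
#'   (default 0.1).
#' @param target_gene,reference_gene Gene labels.
#' @return List with components \code{records} (well-level Cq data.frame),
#'   \code{dilution_series} (named list of data.frames, one per gene),
#'   \code{design_map} (sample-to-condition data.frame) and
#'   \code{control_samples}.
#' @export
simulate_qpcr_experiment <- function(design,
                                     curve_slope = -1 / log10(2),
                                     curve_intercept = 25,
                                     reference_level = 1,
                                     cq_noise_sd = 0.1,
                                     target_gene = "RAG1",
                                     reference_gene = "GAPDH") {
  stopifnot(inherits(design, "sim_design"), curve_slope < 0,
            cq_noise_sd >= 0)
  cq_of <- function(q) curve_intercept + curve_slope * log10(q)
  .with_seed(design$seed + 1L, {
    recs <- list()
    dmap <- list()
    for (cmp in names(design$b)) {
      for (st in names(design$a)) {
        for (x in design$concentrations[[cmp]]) {
          m_true <- expo_response(x, design$a[[st]], design$b[[cmp]],
                                  design$c, design$d)
          q_t <- reference_level * .rlnorm_mean_cv(design$n_replicates,
                                                   m_true, design$cv)
          for (r in seq_len(design$n_replicates)) {
            smp <- paste(cmp, st, x, r, sep = "_")
            noise <- stats::rnorm(2, 0, cq_noise_sd)
            recs[[length(recs) + 1L]] <- data.frame(
              sample = smp,
              gene = c(target_gene, reference_gene),
              cq = c(cq_of(q_t[r]) + noise[1],
                     cq_of(reference_level) + noise[2]),
              stringsAsFactors = FALSE)
            dmap[[length(dmap) + 1L]] <- data.frame(
              sample = smp, compound = cmp, study = st, concentration = x,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    dil <- 2^-(0:4)
    series <- lapply(stats::setNames(c(target_gene, reference_gene),
                                     c(target_gene, reference_gene)),
                     function(g) data.frame(
                       dilution = dil,
                       cq = cq_of(dil) + stats::rnorm(length(dil), 0,
                                                      cq_noise_sd)))
    dmap <- do.call(rbind, dmap)
    list(records = do.call(rbind, recs),
         dilution_series = series,
         design_map = dmap,
         control_samples = dmap$sample[dmap$concentration == 0])
  })
}
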
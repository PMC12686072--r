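# Synthetic cohort generator. Emulates the statistical structure the
# subtyping method exploits: three latent EMT states with separated
# epithelial/mesenchymal panel means, negative epithelial-mesenchymal
# coupling in normal tissue versus joint upregulation with decoupling in
# tumors, paired normal-tumor designs with a configurable state-transition
# matrix, subtype-dependent exponential survival with uniform right
# censoring, and multinomial single-cell type counts.

#' Default simulation parameters
#'
#' @param n_samples Cohort size (unpaired mode).
#' @param n_pairs Number of patients in paired mode.
#' @param prevalence_normal,prevalence_tumor Subtype prevalences
#'   (EPC, HPC, MPC); defaults echo the shift from an EPC-dominated normal
#'   tissue distribution toward an HPC-dominated tumor distribution.
#' @param a Epithelial-axis separation between the polar states, on the
#'   latent (z-like) scale: epithelial panel means are +a (EPC) and -a
#'   (MPC), mesenchymal means the negative (tight anti-coupling).
#' @param b Tumor joint-upregulation offset added to both sub-panels.
#' @param hybrid_level,hybrid_fraction The hybrid (partial-EMT) state
#'   deploys both programs partially and differentially: the first
#'   \code{hybrid_fraction} of each sub-panel's genes sit at
#'   \code{+hybrid_level * a}, the remainder at \code{-hybrid_level * a}.
#'   This gives the hybrid state a correlation profile orthogonal to the
#'   polar epithelial-mesenchymal axis (a uniform intermediate offset
#'   would be invisible to Pearson distance), and hybrid-rich tumor
#'   cohorts consequently show weaker epithelial-mesenchymal
#'   anticorrelation than normal cohorts.
#' @param sigma Gaussian noise sd for every gene.
#' @param n_background Number of uninformative background genes.
#' @param transition 3x3 row-stochastic matrix of normal-state ->
#'   tumor-state transition probabilities (rows/cols EPC, HPC, MPC).
#' @param hazards Monthly event hazards per subtype.
#' @param followup_max Censoring-time upper bound, months.
#' @param cells_per_sample Cells per sample in single-cell mode.
#' @param cell_props_normal,cell_props_tumor Expected cell-type mixture
#'   (epithelial, fibroblast, endothelial, other).
#' @return A parameter list.
#' @export
sim_params <- function(n_samples = 300L,
                       n_pairs = 100L,
                       prevalence_normal = c(0.60, 0.10, 0.30),
                       prevalence_tumor = c(0.35, 0.43, 0.22),
                       a = 1.0,
                       b = 0.5,
                       hybrid_level = 0.75,
                       hybrid_fraction = 0.5,
                       sigma = 0.5,
                       n_background = 200L,
                       transition = matrix(c(0.20, 0.50, 0.30,
                                             0.10, 0.60, 0.30,
                                             0.05, 0.25, 0.70),
                                           nrow = 3, byrow = TRUE,
                                           dimnames = list(SUBTYPES,
                                                           SUBTYPES)),
                       hazards = c(EPC = 0.008, HPC = 0.012, MPC = 0.020),
                       followup_max = 120,
                       cells_per_sample = 2000L,
                       cell_props_normal = c(epithelial = 0.60,
                                             fibroblast = 0.20,
                                             endothelial = 0.10,
                                             other = 0.10),
                       cell_props_tumor = c(epithelial = 0.20,
                                            fibroblast = 0.40,
                                            endothelial = 0.20,
                                            other = 0.20)) {
  p <- list(n_samples = n_samples, n_pairs = n_pairs,
            prevalence_normal = prevalence_normal,
            prevalence_tumor = prevalence_tumor,
            a = a, b = b, hybrid_level = hybrid_level,
            hybrid_fraction = hybrid_fraction, sigma = sigma,
            n_background = n_background, transition = transition,
            hazards = hazards, followup_max = followup_max,
            cells_per_sample = cells_per_sample,
            cell_props_normal = cell_props_normal,
            cell_props_tumor = cell_props_tumor)
  .validate_params(p)
  p
}

.validate_params <- function(p) {
  for (nm in c("prevalence_normal", "prevalence_tumor")) {
    v <- p[[nm]]
    if (length(v) != 3L || any(v < 0) || abs(sum(v) - 1) > 1e-8)
      stop(nm, " must be 3 nonnegative values summing to 1")
  }
  Tm <- p$transition
  if (!is.matrix(Tm) || any(dim(Tm) != 3L) || any(Tm < 0) ||
      any(abs(rowSums(Tm) - 1) > 1e-8))
    stop("transition must be a 3x3 row-stochastic matrix")
  if (p$sigma <= 0) stop("sigma must be positive")
  if (p$a <= 0) stop("a must be positive")
  invisible(TRUE)
}

# Per-gene state means on the latent scale. The polar states sit on the
# anti-coupled EMT axis (epi +a / mes -a for EPC, mirrored for MPC); the
# hybrid state runs a partial-EMT co-expression program: the first
# hybrid_fraction of each sub-panel at hybrid_level * a, the rest at 0.
# Tumor tissue adds the joint upregulation offset b to every panel gene.
.state_mean_vector <- function(p, panel, state, tissue) {
  n_e <- length(panel$epithelial)
  n_m <- length(panel$mesenchymal)
  if (state == "HPC") {
    h <- p$hybrid_level * p$a
    act_e <- seq_len(ceiling(n_e * p$hybrid_fraction))
    act_m <- seq_len(ceiling(n_m * p$hybrid_fraction))
    mu_e <- rep(-h, n_e); mu_e[act_e] <- h
    mu_m <- rep(-h, n_m); mu_m[act_m] <- h
  } else {
    s <- if (state == "EPC") p$a else -p$a
    mu_e <- rep(s, n_e)
    mu_m <- rep(-s, n_m)
  }
  mu <- c(mu_e, mu_m)
  if (tissue == "tumor") mu <- mu + p$b
  mu
}

.gene_names <- function(p, panel) {
  c(panel$epithelial, panel$mesenchymal,
    sprintf("BG%04d", seq_len(p$n_background)))
}

.sample_profile <- function(p, panel, state, tissue) {
  mu <- .state_mean_vector(p, panel, state, tissue)
  c(stats::rnorm(length(mu), mu, p$sigma),
    stats::rnorm(p$n_background, 0, p$sigma))
}

.draw_survival <- function(p, state) {
  t_event <- stats::rexp(1, rate = p$hazards[[state]])
  t_cens <- stats::runif(1, 0, p$followup_max)
  c(time = min(t_event, t_cens), event = as.numeric(t_event <= t_cens))
}

#' Simulate an expression cohort with planted EMT states
#'
#' Each sample draws a latent state by prevalence, panel genes from
#' Gaussians around the state means (with the tumor offset when
#' \code{tissue = "tumor"}), background genes from N(0, sigma), and
#' subtype-dependent exponential survival with uniform right censoring.
#' Fully reproducible from the seed.
#'
#' @param n_samples Cohort size (overrides \code{params}).
#' @param tissue \code{"tumor"} or \code{"normal"}; selects prevalence and
#'   the tumor offset.
#' @param params From [sim_params()].
#' @param seed Integer RNG seed.
#' @param panel Gene panel providing marker names.
#' @return A list: \code{expression} (genes x samples matrix),
#'   \code{meta} (sample table with survival fields), \code{truth}
#'   (data.frame of planted states).
#' @export
simulate_cohort <- function(n_samples = NULL,
                            tissue = c("tumor", "normal"),
                            params = sim_params(), seed = 42L,
                            panel = default_panel()) {
  tissue <- match.arg(tissue)
  .validate_params(params)
  if (!is.null(n_samples)) params$n_samples <- n_samples
  n <- params$n_samples
  set.seed(seed)
  prev <- if (tissue == "tumor") params$prevalence_tumor else
    params$prevalence_normal
  states <- sample(SUBTYPES, n, replace = TRUE, prob = prev)
  ids <- sprintf("S%04d", seq_len(n))
  expr <- vapply(states, function(s)
    .sample_profile(params, panel, s, tissue),
    numeric(length(.gene_names(params, panel))))
  dimnames(expr) <- list(.gene_names(params, panel), ids)
  surv <- t(vapply(states, function(s) .draw_survival(params, s),
                   c(time = 0, event = 0)))
  meta <- data.frame(sample_id = ids,
                     patient_id = ids,
                     tissue = tissue,
                     os_time = unname(surv[, "time"]),
                     os_event = unname(surv[, "event"]),
                     stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, state = states,
                      stringsAsFactors = FALSE)
  list(expression = expr, meta = meta, truth = truth)
}

#' Simulate a paired normal-tumor cohort
#'
#' Per patient, the normal state is drawn from the normal prevalence and
#' the tumor state from the corresponding row of the transition matrix;
#' two expression profiles are generated (the normal one without, the tumor
#' one with the upregulation offset and decoupling).
#'
#' @param n_pairs Number of patients (overrides \code{params}).
#' @param params From [sim_params()].
#' @param seed Integer RNG seed.
#' @param panel Gene panel providing marker names.
#' @return A list: \code{expression}, \code{meta} (with \code{patient_id}
#'   and \code{tissue}), \code{truth} (per-patient normal/tumor states).
#' @export
simulate_paired_cohort <- function(n_pairs = NULL, params = sim_params(),
                                   seed = 42L, panel = default_panel()) {
  .validate_params(params)
  if (!is.null(n_pairs)) params$n_pairs <- n_pairs
  n <- params$n_pairs
  set.seed(seed)
  normal_state <- sample(SUBTYPES, n, replace = TRUE,
                         prob = params$prevalence_normal)
  tumor_state <- vapply(normal_state, function(s)
    sample(SUBTYPES, 1, prob = params$transition[s, ]), "")
  pid <- sprintf("P%04d", seq_len(n))
  ids <- c(paste0(pid, "_N"), paste0(pid, "_T"))
  gn <- .gene_names(params, panel)
  expr <- matrix(0, length(gn), 2L * n, dimnames = list(gn, ids))
  for (i in seq_len(n)) {
    expr[, i] <- .sample_profile(params, panel, normal_state[i], "normal")
    expr[, n + i] <- .sample_profile(params, panel, tumor_state[i], "tumor")
  }
  meta <- data.frame(sample_id = ids,
                     patient_id = c(pid, pid),
                     tissue = rep(c("normal", "tumor"), each = n),
                     stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = pid,
                      normal_state = unname(normal_state),
                      tumor_state = unname(tumor_state),
                      stringsAsFactors = FALSE)
  list(expression = expr, meta = meta, truth = truth)
}

#' Simulate annotated single-cell type counts
#'
#' Per sample, multinomial counts over cell types; tumor samples use a
#' mixture with a lower expected epithelial fraction than normal samples.
#'
#' @param n_per_group Samples per tissue group.
#' @param params From [sim_params()].
#' @param seed Integer RNG seed.
#' @return Data.frame: sample_id, tissue, and one count column per cell
#'   type.
#' @export
simulate_cell_counts <- function(n_per_group = 30L, params = sim_params(),
                                 seed = 42L) {
  .validate_params(params)
  set.seed(seed)
  draw <- function(tissue, props, i) {
    cnt <- as.vector(stats::rmultinom(1, params$cells_per_sample, props))
    data.frame(sample_id = sprintf("%s%03d",
                                   if (tissue == "normal") "N" else "T", i),
               tissue = tissue,
               epithelial = cnt[1], fibroblast = cnt[2],
               endothelial = cnt[3], other = cnt[4],
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(seq_len(n_per_group), function(i)
    draw("normal", params$cell_props_normal, i)),
    lapply(seq_len(n_per_group), function(i)
      draw("tumor", params$cell_props_tumor, i)))
  do.call(rbind, rows)
}
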
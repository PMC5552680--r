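#' Simulate a two-class expression matrix with planted signal
#'
#' Generates a genes x samples matrix mimicking normalised expression data:
#' baseline gene means are log-normal (drawn as Gaussians on the log2
#' scale), every value gets Gaussian log-scale noise, and a chosen number of
#' planted genes are shifted up or down in the case class by
#' `effect_size` noise standard deviations.  With `rpkm_mode = TRUE` the
#' matrix is returned on the linear scale (2^x), mimicking RPKM data.
#'
#' @param n_genes,n_case,n_ctrl dimensions of the dataset.
#' @param planted_up,planted_down number of genes shifted up/down in cases.
#' @param effect_size planted shift in units of `noise_sd` (log2 scale).
#' @param noise_sd per-value Gaussian noise SD (log2 scale).
#' @param base_mean,base_sd mean and SD of the baseline log2 gene means.
#' @param rpkm_mode return a linear-scale matrix instead of log2.
#' @param seed mandatory integer seed; generation is a pure function of the
#'   arguments.
#' @return list with `X` ([expression_matrix()]), `ann`
#'   ([sample_annotation()] data.frame), `planted_up` and `planted_down`
#'   ([gene_set()]s).
#' @export
simulate_two_class <- function(n_genes = 1000, n_case = 20, n_ctrl = 20,
                               planted_up = 10, planted_down = 10,
                               effect_size = 2, noise_sd = 1,
                               base_mean = 7, base_sd = 1.5,
                               rpkm_mode = FALSE, seed) {
  if (missing(seed)) stop("a seed is required")
  if (planted_up + planted_down > n_genes)
    stop("planted gene counts exceed n_genes")
  if (effect_size < 0) stop("effect_size must be >= 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_ctrl)))
  base <- stats::rnorm(n_genes, base_mean, base_sd)
  X <- base + matrix(stats::rnorm(n_genes * (n_case + n_ctrl), 0, noise_sd),
                     n_genes, n_case + n_ctrl)
  up_idx <- seq_len(planted_up)
  down_idx <- planted_up + seq_len(planted_down)
  shift <- effect_size * noise_sd
  if (planted_up)
    X[up_idx, seq_len(n_case)] <- X[up_idx, seq_len(n_case)] + shift
  if (planted_down)
    X[down_idx, seq_len(n_case)] <- X[down_idx, seq_len(n_case)] - shift
  dimnames(X) <- list(genes, samples)
  if (rpkm_mode) X <- 2^X
  ann <- data.frame(sample_id = samples,
                    class_label = rep(c("case", "control"), c(n_case, n_ctrl)),
                    cell_type = rep(c("cancer_line", "healthy_dividing"),
                                    c(n_case, n_ctrl)),
                    origin = "simulated", stringsAsFactors = FALSE)
  list(X = expression_matrix(X, if (rpkm_mode) "linear" else "log"),
       ann = ann,
       planted_up = if (planted_up) gene_set("planted_up", genes[up_idx], "up"),
       planted_down = if (planted_down)
         gene_set("planted_down", genes[down_idx], "down"))
}

#' Simulate regulons driven by correlated latent activities
#'
#' Emulates the situation where the member genes of several regulons
#' co-vary because the controlling factors' activities are correlated
#' across samples.  Each sample draws one latent activity per regulon; the
#' latents share a class-mean shift (cases high) plus correlated
#' within-class noise, and member-gene expression is
#' `baseline + loading x latent + noise`.  The within-class correlation is
#' chosen so that the marginal (across all samples) correlation between any
#' two latents equals `coupling` exactly, which is the quantity an activity
#' estimator should recover.
#'
#' @param n_genes total genes; regulon members occupy disjoint leading
#'   blocks.
#' @param n_case,n_ctrl samples per class.
#' @param regulons named numeric vector of regulon sizes, e.g.
#'   `c(TF_A = 100, TF_B = 100)`.
#' @param coupling target marginal correlation between latent activities,
#'   in \[-1, 1\].
#' @param loading gene expression change per unit latent activity.
#' @param class_shift difference in mean latent activity, cases minus
#'   controls (SD units).  Must be small enough that the required
#'   within-class correlation stays in \[-1, 1\].
#' @param noise_sd residual expression noise SD.
#' @param base_mean,base_sd baseline log2 gene-mean distribution.
#' @param seed mandatory integer seed.
#' @return list with `X`, `ann`, `regulons` (list of [gene_set()]), and
#'   `latents` (samples x regulons matrix of true activities).
#' @export
simulate_latent_regulons <- function(n_genes = 1000, n_case = 30, n_ctrl = 30,
                                     regulons = c(TF_A = 100, TF_B = 100),
                                     coupling = 0.95, loading = 1,
                                     class_shift = 1.5, noise_sd = 0.5,
                                     base_mean = 7, base_sd = 1.5, seed) {
  if (missing(seed)) stop("a seed is required")
  K <- length(regulons)
  if (K < 2) stop("declare at least two regulons")
  if (sum(regulons) > n_genes) stop("regulon sizes exceed n_genes")
  if (abs(coupling) > 1) stop("coupling must be in [-1, 1]")
  # class indicator u = +-1/2 contributes variance s2 = class_shift^2/4 to
  # every latent; within-class correlation solving
  # (rho_w + s2) / (1 + s2) = coupling keeps the marginal correlation exact
  s2 <- class_shift^2 / 4
  rho_w <- coupling * (1 + s2) - s2
  if (rho_w < -1 || rho_w > 1)
    stop("class_shift too large for the requested coupling; reduce it")
  Rw <- matrix(rho_w, K, K); diag(Rw) <- 1
  ch <- tryCatch(chol(Rw), error = function(e) {
    # eigen square root covers the singular limits rho_w = +-1
    eg <- eigen(Rw, symmetric = TRUE)
    if (any(eg$values < -1e-8))
      stop("within-class latent correlation matrix is not positive ",
           "semi-definite; reduce |coupling| or class_shift")
    diag(sqrt(pmax(eg$values, 0)), K) %*% t(eg$vectors)
  })
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- n_case + n_ctrl
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_ctrl)))
  u <- rep(c(0.5, -0.5), c(n_case, n_ctrl))
  Z <- matrix(stats::rnorm(n * K), n, K) %*% ch
  L <- class_shift * u + Z                       # n x K latents
  colnames(L) <- names(regulons); rownames(L) <- samples
  base <- stats::rnorm(n_genes, base_mean, base_sd)
  X <- base + matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n)
  sets <- vector("list", K); names(sets) <- names(regulons)
  offset <- 0L
  for (k in seq_len(K)) {
    idx <- offset + seq_len(regulons[[k]])
    offset <- offset + regulons[[k]]
    X[idx, ] <- X[idx, ] + loading * matrix(L[, k], length(idx), n,
                                            byrow = TRUE)
    sets[[k]] <- gene_set(names(regulons)[k], genes[idx])
  }
  dimnames(X) <- list(genes, samples)
  ann <- data.frame(sample_id = samples,
                    class_label = rep(c("case", "control"), c(n_case, n_ctrl)),
                    cell_type = rep(c("cancer_line", "healthy_dividing"),
                                    c(n_case, n_ctrl)),
                    origin = "simulated", stringsAsFactors = FALSE)
  list(X = expression_matrix(X, "log"), ann = ann, regulons = sets,
       latents = L)
}

#' Toy core metabolic network with hand-checkable ATP yields
#'
#' A deterministic ~16-reaction single-compartment network: glucose
#' exchange feeding a glycolysis lump (glc -> 2 lactate + 2 ATP), lactate
#' exchange and a respiration lump oxidising lactate, oxygen/CO2 exchanges,
#' and for each branched-chain amino acid a transamination step followed by
#' an oxidation lump with a distinct authored ATP yield (Leu 27, Ile 32,
#' Val 24 ATP per unit — fixture constants, not claims about human
#' metabolism), plus a lumped ATP demand.  Full aerobic oxidation of
#' glucose therefore yields 2 + 2 x 14 = 30 ATP, and fermentation-only
#' operation yields exactly 2 ATP per glucose.
#'
#' @return a [metabolic_model()].
#' @export
toy_core_model <- function() {
  rxns <- list(
    EX_glc = list(stoich = c(glc = -1), lb = -10, ub = 0, exchange = TRUE),
    EX_lac = list(stoich = c(lac = -1), lb = 0, ub = 20, exchange = TRUE),
    EX_o2  = list(stoich = c(o2 = -1), lb = -1000, ub = 0, exchange = TRUE),
    EX_co2 = list(stoich = c(co2 = -1), lb = 0, ub = 1000, exchange = TRUE),
    EX_leu = list(stoich = c(leu = -1), lb = -10, ub = 0, exchange = TRUE),
    EX_ile = list(stoich = c(ile = -1), lb = -10, ub = 0, exchange = TRUE),
    EX_val = list(stoich = c(val = -1), lb = -10, ub = 0, exchange = TRUE),
    GLYC  = list(stoich = c(glc = -1, lac = 2, atp = 2), lb = 0, ub = 1000),
    LACOX = list(stoich = c(lac = -1, o2 = -3, co2 = 3, atp = 14),
                 lb = 0, ub = 1000),
    LEUTA = list(stoich = c(leu = -1, kic = 1), lb = 0, ub = 1000),
    LEUOX = list(stoich = c(kic = -1, o2 = -7.5, co2 = 6, atp = 27),
                 lb = 0, ub = 1000),
    ILETA = list(stoich = c(ile = -1, kmv = 1), lb = 0, ub = 1000),
    ILEOX = list(stoich = c(kmv = -1, o2 = -7.5, co2 = 6, atp = 32),
                 lb = 0, ub = 1000),
    VALTA = list(stoich = c(val = -1, kiv = 1), lb = 0, ub = 1000),
    VALOX = list(stoich = c(kiv = -1, o2 = -6.5, co2 = 5, atp = 24),
                 lb = 0, ub = 1000),
    ATPM  = list(stoich = c(atp = -1), lb = 0, ub = 10000))
  metabolic_model(
    metabolites = c("glc", "lac", "o2", "co2", "leu", "ile", "val",
                    "kic", "kmv", "kiv", "atp"),
    reactions = rxns, atp = "atp", inorganic = c("o2", "co2"))
}

#' Simulate NCI-60-like metabolite uptake/secretion tables
#'
#' Draws per-cell-line exchange rates uniformly within the stated ranges,
#' with signs enforced (uptake negative, secretion positive) and lactate
#' secretion parameterised as a fermented fraction of glucose so that every
#' profile is feasible for [toy_core_model()] by construction (lactate <=
#' 2 x glucose uptake).
#'
#' @param n_lines number of cell lines.
#' @param ranges named list of `c(lo, hi)` ranges for `glucose` uptake
#'   magnitude, `ferm_fraction` (fraction of glucose carbon leaving as
#'   lactate, in \[0, 1\]), and `leucine`, `isoleucine`, `valine` uptake
#'   magnitudes.
#' @param seed mandatory integer seed.
#' @return data.frame with columns `cell_line`, `glc`, `lac`, `leu`, `ile`,
#'   `val` (signed rates, metabolite ids matching [toy_core_model()]).
#' @export
simulate_uptake_profiles <- function(n_lines = 20,
                                     ranges = list(glucose = c(0.5, 2),
                                                   ferm_fraction = c(0.3, 0.9),
                                                   leucine = c(0.01, 0.12),
                                                   isoleucine = c(0.01, 0.12),
                                                   valine = c(0.01, 0.12)),
                                     seed) {
  if (missing(seed)) stop("a seed is required")
  need <- c("glucose", "ferm_fraction", "leucine", "isoleucine", "valine")
  miss <- setdiff(need, names(ranges))
  if (length(miss)) stop("ranges must cover: ", paste(miss, collapse = ", "))
  for (nm in need) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0)
      stop("range for '", nm, "' must be c(lo, hi) with 0 <= lo <= hi")
  }
  if (ranges$ferm_fraction[2] > 1)
    stop("ferm_fraction must stay within [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  runif2 <- function(r) stats::runif(n_lines, r[1], r[2])
  g <- runif2(ranges$glucose)
  phi <- runif2(ranges$ferm_fraction)
  data.frame(cell_line = sprintf("line_%02d", seq_len(n_lines)),
             glc = -g, lac = 2 * g * phi,
             leu = -runif2(ranges$leucine),
             ile = -runif2(ranges$isoleucine),
             val = -runif2(ranges$valine),
             stringsAsFactors = FALSE)
}

#' A documented profile family sweeping the BCAA ATP share
#'
#' Holds glucose uptake and the fermented fraction fixed and increases the
#' three branched-chain amino-acid uptakes linearly from zero to
#' `bcaa_max`.  Along this family the summed BCAA ATP fraction computed by
#' [atp_accounting()] increases strictly and spans a wide interval,
#' mirroring the spread seen across tumour cell lines.
#'
#' @param n number of profiles.
#' @param glucose fixed glucose uptake magnitude.
#' @param ferm_fraction fixed fermented fraction of glucose.
#' @param bcaa_max largest per-acid uptake magnitude.
#' @return data.frame in the format of [simulate_uptake_profiles()].
#' @export
bcaa_sweep_profiles <- function(n = 8, glucose = 1, ferm_fraction = 0.9,
                                bcaa_max = 0.15) {
  t <- seq(0, bcaa_max, length.out = n)
  data.frame(cell_line = sprintf("sweep_%02d", seq_len(n)),
             glc = -glucose, lac = 2 * glucose * ferm_fraction,
             leu = -t, ile = -t, val = -t, stringsAsFactors = FALSE)
}
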
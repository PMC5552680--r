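# Independent reference computations used across the test files.  Each
# oracle is coded from the defining formula, not by calling the package.

# dense shrinkage-LDA direction: the textbook formula with a full p x p solve
ref_direction <- function(X, case_idx, ctrl_idx, gamma) {
  mu1 <- rowMeans(X[, case_idx, drop = FALSE])
  mu2 <- rowMeans(X[, ctrl_idx, drop = FALSE])
  delta <- mu1 - mu2
  d <- length(case_idx) + length(ctrl_idx) - 2
  C <- cbind(X[, case_idx, drop = FALSE] - mu1,
             X[, ctrl_idx, drop = FALSE] - mu2)
  Sigma <- tcrossprod(C) / d
  R <- (1 - gamma) * Sigma + gamma * diag(nrow(X))
  b <- solve(R, delta)
  b <- b / sqrt(sum(b^2))
  if (sum(b * delta) < 0) b <- -b
  b
}

# textbook Pearson correlation
ref_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - mean(x); sy <- y - mean(y)
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# Spearman via midranks and the Pearson formula on ranks
ref_spearman <- function(x, y) {
  ref_pearson(rank(x, ties.method = "average"),
              rank(y, ties.method = "average"))
}

# BH step-up by direct hand execution: q_(i) = min_{j >= i} p_(j) * m / j
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric tail: enumerate every size-n subset of 1..N with
# the first D elements "annotated" and count the overlap condition
ref_overlap_p <- function(k, n, D, N, side) {
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= D)
  if (side == "greater") mean(ov >= k) else mean(ov <= k)
}

# pFBA objectives via scipy.optimize.linprog (HiGHS) on a differently
# formulated LP: native bounds, epigraph variables t >= |v|, no splitting.
# One python call evaluates all profiles.  Returns NA for infeasible rows.
py_pfba_objectives <- function(model, profiles_fixed) {
  payload <- list(S = unname(as.matrix(model$S)),
                  lb = unname(model$lb), ub = unname(model$ub),
                  fixed = lapply(profiles_fixed, function(fx)
                    list(idx = unname(match(names(fx), model$rxns)),
                         val = unname(fx))))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = FALSE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "d = json.load(open(sys.argv[1]))",
    "S = np.array(d['S'], dtype=float)",
    "m, n = S.shape",
    "out = []",
    "for fx in d['fixed']:",
    "    lb = np.array(d['lb'], dtype=float); ub = np.array(d['ub'], dtype=float)",
    "    for i, v in zip(fx['idx'], fx['val']):",
    "        lb[i-1] = ub[i-1] = v",
    "    # min sum(t) s.t. S v = 0, v-t <= 0, -v-t <= 0",
    "    c = np.r_[np.zeros(n), np.ones(n)]",
    "    Aeq = np.c_[S, np.zeros((m, n))]",
    "    I = np.eye(n)",
    "    Aub = np.r_[np.c_[I, -I], np.c_[-I, -I]]",
    "    bub = np.zeros(2 * n)",
    "    bounds = [(l, u) for l, u in zip(lb, ub)] + [(0, None)] * n",
    "    r = linprog(c, A_ub=Aub, b_ub=bub, A_eq=Aeq, b_eq=np.zeros(m),",
    "                bounds=bounds, method='highs')",
    "    out.append(r.fun if r.status == 0 else None)",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, fin, fout), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0) stop("python/scipy oracle failed")
  vals <- jsonlite::read_json(fout, simplifyVector = TRUE)
  unlist(lapply(vals, function(v) if (is.null(v)) NA_real_ else v))
}

# translate a metabolite-keyed profile into fixed exchange-reaction fluxes
profile_to_fixed <- function(model, profile) {
  emap <- chardir::exchange_map(model)
  fx <- as.numeric(profile)
  names(fx) <- emap[names(profile)]
  fx
}

# hand-derived unique flux solution of the toy core network for a profile
# (glc uptake g, lactate secretion l, BCAA uptakes a1..a3): every internal
# flux is pinned by the balances, so Sum|v| has a closed form
ref_toy_objective <- function(g, l, a1, a2, a3) {
  lacox <- 2 * g - l
  o2 <- 3 * lacox + 7.5 * a1 + 7.5 * a2 + 6.5 * a3
  co2 <- 3 * lacox + 6 * a1 + 6 * a2 + 5 * a3
  atpm <- 2 * g + 14 * lacox + 27 * a1 + 32 * a2 + 24 * a3
  sum(abs(c(-g, l, -o2, co2, -a1, -a2, -a3,        # exchanges
            g, lacox, a1, a1, a2, a2, a3, a3,      # internal pathway
            atpm)))
}
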
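# Empirical amino-acid substitution models: exchangeabilities with model or
# observed (+F) frequencies, discrete-gamma rate heterogeneity and an
# optional finite profile mixture standing in for site-heterogeneous models.
#
# Exchangeability/frequency tables for LG and WAG come from phangorn's
# built-in model collection.

# fetch the lower-triangle exchangeabilities and model frequencies
fetch_empirical_model <- function(name) {
  Q <- NULL; bf <- NULL
  phangorn_get <- get("getModelAA", envir = asNamespace("phangorn"))
  phangorn_get(name, bf = TRUE, Q = TRUE)
  # getModelAA assigns Q (190 lower-triangle rates) and bf (20 frequencies)
  # into the calling frame
  list(rates = Q, freqs = bf)
}

lower_tri_to_sym <- function(rates) {
  S <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  S[lower.tri(S)] <- rates
  S <- S + t(S)
  S
}

#' Equal-probability discrete-gamma category rates
#'
#' K categories with equal weight 1/K; each category's rate is the
#' conditional mean of a Gamma(shape, rate = shape) distribution within its
#' probability quantile band, so the category rates average exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (alpha <= 0) stop("gamma shape must be positive")
  if (k < 1) stop("need at least one rate category")
  if (k == 1L) return(1)
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X | a < X < b] for X ~ Gamma(alpha, alpha) via the incomplete-gamma
  # identity: integral of x f(x) equals P(alpha+1) mass at rate alpha
  upper <- stats::pgamma(breaks[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(breaks[-(k + 1)], shape = alpha + 1, rate = alpha)
  r <- k * (upper - lower)
  r / mean(r) * 1  # guard against roundoff; mean is already 1 analytically
}

#' Build an amino-acid substitution model
#'
#' Constructs a reversible rate matrix `Q = S diag(pi)` from an empirical
#' exchangeability table, normalised so the expected substitution rate at
#' stationarity is 1, with discrete-gamma rate heterogeneity and optionally a
#' finite mixture of frequency profiles (each profile gets its own normalised
#' rate matrix; components are weighted in the site likelihood).
#'
#' @param name `"LG"` or `"WAG"`.
#' @param freq_mode `"model"` (the table's frequencies) or `"empirical"`
#'   (+F: observed residue proportions of `aln`, with pseudocount 0.5 for any
#'   absent residue, renormalised).
#' @param alpha Gamma shape for among-site rate variation (default 0.5).
#' @param k Number of discrete-gamma categories (default 4).
#' @param aln Alignment, required when `freq_mode = "empirical"`.
#' @param mixture Optional list of components, each
#'   `list(freqs = <20 numbers summing to 1>, weight = w)`; weights must sum
#'   to 1. When supplied it replaces the single frequency vector.
#' @return An object of class `aa_model`.
#' @examples
#' m <- build_model("LG", alpha = 0.5, k = 4)
#' sum(m$cat_rates * m$cat_weights)  # 1
#' @export
build_model <- function(name = c("LG", "WAG"),
                        freq_mode = c("model", "empirical"),
                        alpha = 0.5, k = 4L, aln = NULL, mixture = NULL) {
  name <- match.arg(name)
  freq_mode <- match.arg(freq_mode)
  if (!is.numeric(alpha) || alpha <= 0) stop("config error: alpha must be > 0")
  if (k < 1) stop("config error: need k >= 1 rate categories")
  emp <- fetch_empirical_model(name)
  S <- lower_tri_to_sym(emp$rates)

  if (is.null(mixture)) {
    freqs <- if (freq_mode == "model") {
      emp$freqs
    } else {
      if (is.null(aln)) stop("empirical (+F) frequencies require an alignment")
      empirical_freqs(aln)
    }
    components <- list(list(freqs = freqs, weight = 1))
  } else {
    w <- vapply(mixture, function(cm) cm$weight, 0)
    if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
    components <- lapply(mixture, function(cm) {
      f <- cm$freqs / sum(cm$freqs)
      list(freqs = f, weight = cm$weight)
    })
  }

  components <- lapply(components, function(cm) {
    c(cm, build_component(S, cm$freqs))
  })

  structure(list(
    name = name,
    freq_mode = if (is.null(mixture)) freq_mode else "mixture",
    S = S,
    alpha = alpha,
    k = as.integer(k),
    cat_rates = discrete_gamma_rates(alpha, k),
    cat_weights = rep(1 / k, k),
    components = components
  ), class = "aa_model")
}

# eigen machinery for one frequency profile: Q = S diag(pi), expected rate 1.
# Reversibility makes diag(sqrt(pi)) Q diag(1/sqrt(pi)) symmetric, giving a
# real spectrum and a stable P(t).
build_component <- function(S, freqs) {
  if (length(freqs) != 20L || any(freqs < 0)) stop("invalid frequency vector")
  freqs <- freqs / sum(freqs)
  Q <- S * rep(freqs, each = 20)        # Q_ab = S_ab * pi_b
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))           # expected rate at stationarity
  Q <- Q / mu
  sp <- sqrt(freqs)
  B <- Q * (sp %o% (1 / sp))            # diag(sqrt pi) Q diag(1/sqrt pi)
  B <- (B + t(B)) / 2                   # symmetrise away roundoff
  eig <- eigen(B, symmetric = TRUE)
  list(Q = Q,
       eigenvalues = eig$values,
       V = eig$vectors / sp,            # diag(1/sqrt pi) U
       Vinv = t(eig$vectors) * rep(sp, each = 20))  # U' diag(sqrt pi)
}

#' Observed residue frequencies of an alignment (+F)
#'
#' Proportions of the 20 residues over all non-ambiguous cells, with a
#' pseudocount of 0.5 for each residue absent from the alignment,
#' renormalised.
#'
#' @param aln An [aa_alignment()].
#' @return Numeric vector of 20 frequencies summing to 1.
#' @export
empirical_freqs <- function(aln) {
  counts <- table(factor(unclass(aln), levels = aa_alphabet()))
  counts <- as.numeric(counts)
  counts[counts == 0] <- 0.5
  counts / sum(counts)
}

#' Transition probability matrix P(t)
#'
#' @param model An [build_model()] object.
#' @param t Branch length (>= 0), in expected substitutions per site.
#' @param rate Rate multiplier (site-rate category), >= 0.
#' @param component Mixture component index (default 1).
#' @return 20x20 row-stochastic matrix; `P(0)` is the identity and
#'   `pi_a P_ab = pi_b P_ba` (detailed balance).
#' @export
transition_matrix <- function(model, t, rate = 1, component = 1L) {
  if (t < 0) stop("negative branch length")
  if (rate < 0) stop("negative rate multiplier")
  cm <- model$components[[component]]
  P <- cm$V %*% (exp(cm$eigenvalues * t * rate) * cm$Vinv)
  P[P < 0] <- 0                          # clip eigen-roundoff
  P <- P / rowSums(P)
  dimnames(P) <- list(aa_alphabet(), aa_alphabet())
  P
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name,
      switch(x$freq_mode, model = "(model frequencies)",
             empirical = "+F (observed frequencies)",
             mixture = sprintf("+ %d-profile mixture", length(x$components))),
      "\n")
  cat(sprintf("  gamma shape %.4g with %d categories; rates: %s\n",
              x$alpha, x$k, paste(sprintf("%.3f", x$cat_rates), collapse = " ")))
  invisible(x)
}

model_stationary_freqs <- function(model) {
  w <- vapply(model$components, `[[`, 0, "weight")
  f <- sapply(model$components, `[[`, "freqs")
  as.numeric(f %*% w)
}
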
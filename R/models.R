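#' Amino-acid substitution models
#'
#' Two time-reversible 20-state models are provided. `"eq20"` is the
#' equal-rates model (the 20-state analogue of Jukes-Cantor): all
#' exchangeabilities equal, uniform stationary frequencies, and closed-form
#' transition probabilities, which makes it the model of choice for tests
#' with analytic oracles. `"lg"` is the empirical LG exchangeability matrix
#' with its stationary frequencies (taken from phangorn's model table),
#' provided for realism. Rate matrices are scaled so branch lengths are in
#' expected substitutions per site.
#'
#' @param id model identifier, "eq20" or "lg".
#' @return object of class `subst_model` with elements `id`, `bf`
#'   (stationary frequencies in the A R N D C Q E G H I L K M F P S T W Y V
#'   order) and, for non-analytic models, a cached eigendecomposition of the
#'   rate matrix.
#' @export
subst_model <- function(id = c("eq20", "lg")) {
  id <- match.arg(id)
  if (id == "eq20") {
    m <- list(id = "eq20", bf = rep(1 / 20, 20), eig = NULL)
  } else {
    lg <- get(".LG", envir = asNamespace("phangorn"))
    bf <- as.numeric(lg$bf)
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- lg$Q
    S <- S + t(S)
    Q <- S * rep(bf, each = 20)      # Q_ij = s_ij * pi_j
    diag(Q) <- -rowSums(Q)
    Q <- Q / sum(-diag(Q) * bf)      # unit expected rate
    # symmetric similarity transform for a stable eigendecomposition
    sq <- sqrt(bf)
    B <- Q * outer(sq, 1 / sq)
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    m <- list(id = "lg", bf = bf,
              eig = list(values = e$values,
                         U = e$vectors * (1 / sq),
                         Uinv = t(e$vectors * sq)))
  }
  class(m) <- "subst_model"
  m
}

#' Transition probability matrix P(t)
#'
#' @param model a `subst_model`.
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @return 20 x 20 matrix with rows summing to 1.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(t >= 0)
  if (model$id == "eq20") {
    k <- 20
    e <- exp(-k * t / (k - 1))
    p_same <- 1 / k + (1 - 1 / k) * e
    p_diff <- (1 - e) / k
    P <- matrix(p_diff, k, k)
    diag(P) <- p_same
    P
  } else {
    eg <- model$eig
    P <- eg$U %*% (exp(eg$values * t) * eg$Uinv)
    # numerical floor: exact zeros can occur at t = 0
    P[P < 0] <- 0
    P
  }
}

#' Expected pairwise difference under the equal-rates model
#'
#' Closed form for the probability that two sequences separated by patristic
#' distance `t` differ at a site; used as the analytic oracle for sequence
#' simulation.
#'
#' @param t patristic distance in substitutions per site.
#' @return expected fraction of differing sites.
#' @export
eq20_expected_difference <- function(t) {
  k <- 20
  (k - 1) / k * (1 - exp(-k * t / (k - 1)))
}
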
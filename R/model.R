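## Nucleotide substitution models. States are ordered A, C, G, T; rate
## matrices are scaled so branch lengths are expected substitutions per
## site. Gaps and N (and all other ambiguity codes upstream) are treated
## as missing data in likelihood computations.

DNA_STATES <- c("A", "C", "G", "T")

#' Construct a substitution model
#'
#' @param kind `"JC69"` (default) or `"GTR"`.
#' @param exchangeabilities For GTR: the six exchangeability rates in the
#'   order AC, AG, AT, CG, CT, GT.
#' @param base_freqs For GTR: stationary base frequencies (A, C, G, T);
#'   must sum to 1.
#' @return An object of class `subst_model`.
#' @examples
#' m <- subst_model("JC69")
#' transition_prob(m, 0.1)
#' @export
subst_model <- function(kind = c("JC69", "GTR"),
                        exchangeabilities = NULL, base_freqs = NULL) {
  kind <- match.arg(kind)
  if (kind == "JC69") {
    return(structure(list(kind = "JC69", freqs = rep(0.25, 4)),
                     class = "subst_model"))
  }
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities > 0),
            length(base_freqs) == 4L, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8)
  pi <- base_freqs / sum(base_freqs)
  ## symmetric exchangeability matrix, order AC, AG, AT, CG, CT, GT
  s <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    s[pairs[k, 1], pairs[k, 2]] <- exchangeabilities[k]
    s[pairs[k, 2], pairs[k, 1]] <- exchangeabilities[k]
  }
  q <- s %*% diag(pi)
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))            # expected rate; rescale to 1
  q <- q / mu
  ## eigendecomposition of the symmetrized generator for fast expm
  d_sqrt <- diag(sqrt(pi))
  d_isqrt <- diag(1 / sqrt(pi))
  sym <- d_sqrt %*% q %*% d_isqrt
  eig <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  structure(list(kind = "GTR", freqs = pi, rates = exchangeabilities,
                 q = q, evec = d_isqrt %*% eig$vectors,
                 ivec = t(eig$vectors) %*% d_sqrt, evals = eig$values),
            class = "subst_model")
}

#' Transition probability matrix P(t)
#'
#' @param model A [subst_model()].
#' @param t Branch length in expected substitutions per site.
#' @return A 4x4 row-stochastic matrix, rows = from-state (A,C,G,T).
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), t >= 0)
  if (model$kind == "JC69") {
    e <- exp(-4 * t / 3)
    p_same <- 0.25 + 0.75 * e
    p_diff <- 0.25 - 0.25 * e
    p <- matrix(p_diff, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
    diag(p) <- p_same
    return(p)
  }
  p <- model$evec %*% diag(exp(model$evals * t)) %*% model$ivec
  p[p < 0] <- 0                       # clip eigen round-off
  dimnames(p) <- list(DNA_STATES, DNA_STATES)
  p
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: %s\n", x$kind))
  cat("  base frequencies:", paste(format(x$freqs, digits = 4), collapse = " "), "\n")
  invisible(x)
}

## Encode a gapped sequence as state indices 1..4; gaps, N and anything
## else become NA (missing data).
encode_states <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- match(chars, DNA_STATES)
  m
}
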
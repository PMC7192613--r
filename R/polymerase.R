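#' In vitro ribonucleotide incorporation frequencies of steric-gate
#' polymerase variants
#'
#' Frequencies are expressed as rNMPs per dNMP synthesized: 1/40 for Pol
#' alpha L868M, 1/300 for Pol delta L612M and 1/100 for Pol epsilon M644G.
#'
#' @return Named numeric vector with elements `alpha`, `delta`, `epsilon`.
#' @export
pol_incorporation_freqs <- function() {
  c(alpha = 1 / 40, delta = 1 / 300, epsilon = 1 / 100)
}

#' Contribution of replicative polymerases to genome synthesis
#'
#' Deconvolves the share of nuclear DNA synthesized by Pols alpha, delta
#' and epsilon from total genomic ribonucleotide counts of RNase-H2-null
#' strains.  For each polymerase, the excess ribonucleotides introduced by
#' its rNTP-permissive (steric-gate) variant over the all-wild-type-Pol
#' strain, `dN = N_polx - N_base`, is divided by the variant's in vitro
#' incorporation frequency `F` to convert ribonucleotide load into
#' nucleotides synthesized; percentages are the weighted terms normalized
#' to their sum:
#' `percent_x = 100 * (dN_x / F_x) / sum_j(dN_j / F_j)`.
#'
#' @param n_base total genomic rNMPs of the RNase-H2-null strain with
#'   wild-type Pols.
#' @param n_pol named numeric vector (`alpha`, `delta`, `epsilon`): total
#'   genomic rNMPs of the matching steric-gate-variant strains.  Each must
#'   be at least `n_base`.
#' @param freqs named incorporation frequencies (rNMP per dNMP); default
#'   [pol_incorporation_freqs()].
#' @param se_base,se_pol optional standard errors of `n_base` and `n_pol`
#'   for first-order error propagation onto the percentages.
#'
#' @return An object of class `pol_contrib` with elements `delta_n`,
#'   `weighted` (`dN/F`), `percent` (sums to 100),
#'   `ratio_delta_over_epsilon`, and `percent_se` when errors were given.
#'
#' @examples
#' pol_contributions(8403,
#'                   c(alpha = 15007, delta = 20136, epsilon = 18316))
#' @export
pol_contributions <- function(n_base, n_pol,
                              freqs = pol_incorporation_freqs(),
                              se_base = NULL, se_pol = NULL) {
  pols <- names(freqs)
  if (is.null(names(n_pol)) || !all(pols %in% names(n_pol))) {
    missing <- setdiff(pols, names(n_pol) %||% character(0))
    stop("missing polymerase totals: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_pol <- n_pol[pols]
  if (any(freqs <= 0)) stop("incorporation frequencies must be > 0",
                            call. = FALSE)
  dn <- n_pol - n_base
  if (any(dn < 0)) {
    stop("strain total below base strain for: ",
         paste(pols[dn < 0], collapse = ", "),
         " (inconsistent inputs)", call. = FALSE)
  }
  w <- dn / freqs
  S <- sum(w)
  if (S <= 0) stop("all excess ribonucleotide counts are zero",
                   call. = FALSE)
  pct <- 100 * w / S
  out <- list(delta_n = dn, weighted = w, percent = pct,
              ratio_delta_over_epsilon = unname(w["delta"] / w["epsilon"]),
              freqs = freqs, n_base = n_base, n_pol = n_pol)
  if (!is.null(se_pol)) {
    se_base <- se_base %||% 0
    var_dn <- (se_pol[pols])^2 + se_base^2
    var_w <- var_dn / freqs^2
    # gradient of pct_i wrt w: d pct_i/d w_i = 100 (S - w_i)/S^2,
    #                          d pct_i/d w_j = -100 w_i / S^2
    out$percent_se <- vapply(seq_along(w), function(i) {
      g <- -100 * w[i] / S^2 * rep(1, length(w))
      g[i] <- 100 * (S - w[i]) / S^2
      sqrt(sum(g^2 * var_w))
    }, numeric(1))
    names(out$percent_se) <- pols
  }
  structure(out, class = "pol_contrib")
}

#' @export
print.pol_contrib <- function(x, ...) {
  cat("Replicative polymerase contributions to genome synthesis\n")
  tab <- data.frame(pol = names(x$percent),
                    delta_N = round(unname(x$delta_n), 1),
                    freq = sprintf("1/%g", 1 / x$freqs),
                    weighted = round(unname(x$weighted)),
                    percent = round(unname(x$percent), 2))
  if (!is.null(x$percent_se)) tab$percent_se <- round(unname(x$percent_se), 2)
  print(tab, row.names = FALSE)
  cat(sprintf("  Pol delta : Pol epsilon = %.2f-fold\n",
              x$ratio_delta_over_epsilon))
  invisible(x)
}
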
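#' Upper-tail binomial probability
#'
#' The over-representation statistic: the probability of observing `k` or
#' more successes in `n` independent trials with success probability
#' `p_success`, i.e. `P(X >= k)` for `X ~ Binomial(n, p_success)`. In the
#' analysis, `n` is the number of distinct mapped sample entities,
#' `p_success = T/N` the fraction of the species background curated in the
#' pathway, and `k` the sample entities found in it — the one-sided tail
#' asks whether the found proportion exceeds random expectation.
#'
#' Computed through the binomial survival function, which is numerically
#' stable for small tail probabilities (no naive summation of tiny terms).
#'
#' @param k non-negative integer(s), successes observed (`k <= n`).
#' @param n non-negative integer(s), number of trials.
#' @param p_success success probability in `[0, 1]`.
#' @return `P(X >= k)`, vectorised over the inputs.
#' @examples
#' binomial_tail(2, 10, 0.1)   # 0.2639011
#' binomial_tail(0, 10, 0.99)  # 1: the whole distribution
#' @export
binomial_tail <- function(k, n, p_success) {
  if (any(k < 0) || any(n < 0) || any(k > n)) {
    stop("binomial_tail(): need 0 <= k <= n", call. = FALSE)
  }
  if (any(p_success < 0) || any(p_success > 1) || any(is.na(p_success))) {
    stop("binomial_tail(): p_success must be in [0, 1]", call. = FALSE)
  }
  # P(X >= k) = 1 - P(X <= k - 1); survival form avoids cancellation
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, p_success, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' The standard step-up procedure: with `m` p-values sorted ascending,
#' `adjusted_(i) = min_{j >= i} ( p_(j) * m / j )` capped at 1, mapped back
#' to the input order. Tied p-values share their adjusted value.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("bh_adjust(): p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  scaled <- p_values[o] * m / seq_len(m)
  adjusted <- rev(cummin(rev(scaled)))
  adjusted <- pmin(adjusted, 1)
  out <- numeric(m)
  out[o] <- adjusted
  out
}

#' Compute per-pathway enrichment statistics
#'
#' Turns a filled analysis state into the result table: one row per pathway
#' with a non-zero curated total in each analysed species, carrying
#' `k` (sample entities found, `|found_entities|`), `T` (curated total),
#' `n` (distinct mapped sample entities in the species background), `N`
#' (background size), the binomial tail p-value with success probability
#' `T/N`, and the Benjamini-Hochberg FDR computed once across all emitted
#' rows of the analysis. Rows are sorted by ascending p-value, ties broken
#' by pathway id. Pathways with `T = 0` are untestable and excluded from
#' the rows and from the correction's `m`.
#'
#' @param state an `analysis_state` whose hits have been marked
#'   (see [mark_hit()]); carries its forest (with totals and backgrounds).
#' @param n_by_species named integer vector: analysed species -> `n`.
#' @return data frame with columns `pathway_id`, `pathway_name`, `species`,
#'   `entities_found`, `entities_total`, `sample_mapped`, `background`,
#'   `p_value`, `fdr` and a list column `found` of found main identifiers.
#' @export
compute_statistics <- function(state, n_by_species) {
  forest <- state$forest
  rows <- list()
  for (sp in names(n_by_species)) {
    if (!sp %in% forest$species) {
      stop(sprintf("species '%s' has no pathway data", sp), call. = FALSE)
    }
    N <- forest$background[[sp]]
    if (is.na(N) || N == 0L) {
      stop(sprintf("empty knowledge-base background for species '%s'", sp),
           call. = FALSE)
    }
    n <- n_by_species[[sp]]
    for (pid in forest$pathway_ids) {
      node <- forest$nodes[[pid]]
      if (node$species != sp || node$total_entities == 0L) next
      found <- found_entities(state, pid)
      rows[[length(rows) + 1L]] <- list(
        pathway_id = pid,
        pathway_name = node$name,
        species = sp,
        entities_found = length(found),
        entities_total = node$total_entities,
        sample_mapped = as.integer(n),
        background = as.integer(N),
        p_value = binomial_tail(length(found), n, node$total_entities / N),
        found = found
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      pathway_id = character(0), pathway_name = character(0),
      species = character(0), entities_found = integer(0),
      entities_total = integer(0), sample_mapped = integer(0),
      background = integer(0), p_value = numeric(0), fdr = numeric(0)
    ))
  }
  df <- data.frame(
    pathway_id = vapply(rows, `[[`, character(1), "pathway_id"),
    pathway_name = vapply(rows, `[[`, character(1), "pathway_name"),
    species = vapply(rows, `[[`, character(1), "species"),
    entities_found = vapply(rows, `[[`, integer(1), "entities_found"),
    entities_total = vapply(rows, `[[`, integer(1), "entities_total"),
    sample_mapped = vapply(rows, `[[`, integer(1), "sample_mapped"),
    background = vapply(rows, `[[`, integer(1), "background"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  df$fdr <- bh_adjust(df$p_value)
  df$found <- lapply(rows, `[[`, "found")
  ord <- order(df$p_value, df$pathway_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
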
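.GRADES <- c("LGD", "HGD", "IC")

#' Cohort composition by dysplasia grade
#'
#' Counts and percentages per grade (rounded half-up to 2 decimals, the
#' printed-table convention), plus the T1a share of the invasive-cancer
#' subgroup.
#'
#' @param cohort data.frame with columns `grade` (LGD/HGD/IC), `t_stage`
#'   (NA outside IC), `tnfa_pg_ml`.
#' @return list(`table` = data.frame(grade, n, pct), `t1a_pct` (of IC; NA if
#'   no IC), `n_total`).
#' @export
cohort_composition <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort")
  g <- as.character(cohort$grade)
  unknown <- setdiff(unique(g), .GRADES)
  if (length(unknown))
    stop("unknown grade label(s): ", paste(unknown, collapse = ", "))
  n <- vapply(.GRADES, function(x) sum(g == x), numeric(1))
  present <- .GRADES[n > 0]
  tab <- data.frame(grade = present, n = n[present],
                    pct = .round_half_up(100 * n[present] / sum(n), 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  ic <- g == "IC"
  t1a_pct <- if (any(ic))
    .round_half_up(100 * sum(cohort$t_stage[ic] == "T1a", na.rm = TRUE) /
                     sum(ic), 2) else NA_real_
  list(table = tab, t1a_pct = t1a_pct, n_total = sum(n))
}

#' Per-grade median and interquartile range of the biomarker
#'
#' Median and IQR bounds use the 50th/25th/75th percentiles with linear
#' interpolation (R's default quantile type).
#'
#' @param cohort data.frame as in [cohort_composition()].
#' @return data.frame(grade, n, median, q25, q75).
#' @export
grade_summary <- function(cohort) {
  g <- factor(as.character(cohort$grade), levels = .GRADES)
  out <- lapply(levels(g), function(gr) {
    v <- cohort$tnfa_pg_ml[g == gr]
    if (!length(v)) return(NULL)
    data.frame(grade = gr, n = length(v), median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# U statistic of B over A with midranks for ties
.u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(b) + length(a)]) - length(b) * (length(b) + 1) / 2
}

#' One-tailed Mann-Whitney test
#'
#' Rank-sum U statistic with midranks for ties. The p-value is exact by full
#' enumeration of all group assignments when the combined sample size is at
#' most `exact_max_n` (ties handled exactly), otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' `alternative = "greater"` tests whether B stochastically exceeds A.
#'
#' @param a,b numeric value vectors for the two groups.
#' @param alternative `"greater"` (B exceeds A) or `"less"`.
#' @param exact_max_n combined-size cutoff for the exact path (default 16).
#' @return list(U, p_value, method); U counts pairs (b > a) + ties/2.
#' @export
mw_one_tailed <- function(a, b, alternative = c("greater", "less"),
                          exact_max_n = 16) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    warning("all values identical across both groups; p = 0.5 by convention")
    return(list(U = length(a) * length(b) / 2, p_value = 0.5,
                method = "degenerate"))
  }
  u_obs <- .u_stat(a, b)
  n <- length(a) + length(b); nb <- length(b)
  if (n <= exact_max_n) {
    r <- rank(c(a, b))
    combos <- combn(n, nb)
    offset <- nb * (nb + 1) / 2
    u_all <- colSums(matrix(r[combos], nrow = nb)) - offset
    p <- if (alternative == "greater") mean(u_all >= u_obs - 1e-9)
         else mean(u_all <= u_obs + 1e-9)
    return(list(U = u_obs, p_value = p, method = "exact"))
  }
  na <- length(a)
  mu <- na * nb / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
  z <- if (alternative == "greater") (u_obs - mu - 0.5) / sigma
       else (u_obs - mu + 0.5) / sigma
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
       else pnorm(z)
  list(U = u_obs, p_value = p, method = "normal-approx")
}

#' Grade-merged biomarker contrasts
#'
#' Runs [mw_one_tailed()] for the clinically motivated contrasts: LGD vs
#' HGD; LGD vs IC; LGD vs (HGD + IC restricted to T1a, i.e. high-grade or
#' minimally invasive); LGD vs (HGD + all IC). The alternative is that the
#' more severe arm has higher concentrations. Contrasts with an empty arm
#' are skipped with a message.
#'
#' @param cohort data.frame as in [cohort_composition()].
#' @param alternative direction passed to [mw_one_tailed()].
#' @return data.frame(contrast, n_ref, n_alt, U, p_value, method).
#' @export
merged_contrasts <- function(cohort, alternative = "greater") {
  g <- as.character(cohort$grade)
  v <- cohort$tnfa_pg_ml
  lgd <- v[g == "LGD"]
  t1a <- v[g == "IC" & !is.na(cohort$t_stage) & cohort$t_stage == "T1a"]
  arms <- list(
    "LGD vs HGD" = v[g == "HGD"],
    "LGD vs IC" = v[g == "IC"],
    "LGD vs HGD+IC(T1a)" = if (length(t1a)) c(v[g == "HGD"], t1a),
    "LGD vs HGD+IC" = v[g %in% c("HGD", "IC")])
  rows <- lapply(names(arms), function(nm) {
    alt <- arms[[nm]]
    if (!length(lgd) || !length(alt)) {
      message("contrast '", nm, "' skipped: empty arm")
      return(NULL)
    }
    res <- mw_one_tailed(lgd, alt, alternative = alternative)
    data.frame(contrast = nm, n_ref = length(lgd), n_alt = length(alt),
               U = res$U, p_value = res$p_value, method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
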
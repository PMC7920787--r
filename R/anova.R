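RESPONSE_ATTRIBUTES <- c("n_species", "active_nodes", "n_edges",
                         "density_pct", "sips_intra", "sips_inter",
                         "bips_intra", "bips_inter")

#' Melt network summaries into an ANOVA response table
#'
#' The eight numeric network attributes of each (regime, habitat) summary
#' are treated as replicate responses of that cell, giving a balanced
#' two-factor layout (with the default design: 2 regimes x 5 habitats x 8
#' attributes = 80 rows). Pooling heterogeneous scales as replicates is a
#' deliberate reproduction of the reference analysis; see the methods
#' vignette for the caveat.
#'
#' @param summaries data.frame of [summarize_network()] rows, exactly one
#'   per (regime, habitat) cell.
#' @return data.frame `regime`, `habitat`, `attribute`, `value`.
#' @export
build_response_table <- function(summaries) {
  cell <- paste(summaries$regime, summaries$habitat, sep = "-")
  if (anyDuplicated(cell)) {
    stop("duplicate (regime, habitat) cell: ",
         cell[duplicated(cell)][1], call. = FALSE)
  }
  expected <- as.vector(outer(SBAN_REGIMES, SBAN_HABITATS, paste, sep = "-"))
  missing <- setdiff(expected, cell)
  if (length(missing) > 0) {
    stop("missing (regime, habitat) cell: ", missing[1], call. = FALSE)
  }
  out <- do.call(rbind, lapply(RESPONSE_ATTRIBUTES, function(a) {
    data.frame(regime = summaries$regime, habitat = summaries$habitat,
               attribute = a, value = as.numeric(summaries[[a]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-way fixed-effects ANOVA of network attributes
#'
#' Fits `value ~ regime * habitat` on a balanced response table and returns
#' the SPSS-style between-subjects table: corrected model, intercept, sites
#' (regime), habitat, sites x habitat, error, total, and corrected total,
#' with Type III sums of squares (identical to sequential sums under
#' balance), F ratios against the error mean square, and p-values from the F
#' distribution, plus R-squared and adjusted R-squared.
#'
#' @param table Response table from [build_response_table()].
#' @return List of class `sban_anova` with elements `table` (data.frame
#'   `source`, `ss`, `df`, `ms`, `f`, `p`), `r_squared`,
#'   `adj_r_squared`, `mse`, `df_error`, and the fitted data.
#' @export
anova_two_way <- function(table) {
  counts <- base::table(table$regime, table$habitat)
  if (length(unique(as.vector(counts))) != 1 || any(counts < 2)) {
    stop("unsupported design: expected a balanced two-factor layout with ",
         ">= 2 replicates per cell", call. = FALSE)
  }
  dat <- data.frame(regime = factor(table$regime),
                    habitat = factor(table$habitat),
                    value = table$value)
  fit <- stats::lm(value ~ regime * habitat, data = dat)
  # zero-noise designs trip anova.lm's "essentially perfect fit" warning;
  # the degenerate branch below handles that case explicitly
  a <- suppressWarnings(stats::anova(fit))
  ss <- a$`Sum Sq`
  df <- a$Df
  n <- nrow(dat)
  ss_sites <- ss[1]; ss_hab <- ss[2]; ss_int <- ss[3]; ss_err <- ss[4]
  df_err <- df[4]
  ss_model <- ss_sites + ss_hab + ss_int
  df_model <- df[1] + df[2] + df[3]
  ss_intercept <- n * mean(dat$value)^2
  ss_ctotal <- ss_model + ss_err
  mse <- ss_err / df_err
  src <- function(source, s, d) {
    ms <- s / d
    f <- ms / mse
    data.frame(source = source, ss = s, df = d, ms = ms, f = f,
               p = stats::pf(f, d, df_err, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    src("corrected_model", ss_model, df_model),
    src("intercept", ss_intercept, 1),
    src("sites", ss_sites, df[1]),
    src("habitat", ss_hab, df[2]),
    src("sites_x_habitat", ss_int, df[3]),
    data.frame(source = "error", ss = ss_err, df = df_err, ms = mse,
               f = NA_real_, p = NA_real_, stringsAsFactors = FALSE),
    data.frame(source = "total", ss = ss_ctotal + ss_intercept, df = n,
               ms = NA_real_, f = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(source = "corrected_total", ss = ss_ctotal, df = n - 1,
               ms = NA_real_, f = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE)
  )
  # degenerate all-constant response: effects are exactly 0, report p = 1
  degenerate <- ss_ctotal <= 1e-10 * (ss_intercept + 1)
  if (degenerate) {
    tab$f[tab$source %in% c("corrected_model", "sites", "habitat",
                            "sites_x_habitat")] <- 0
    tab$p[tab$source %in% c("corrected_model", "sites", "habitat",
                            "sites_x_habitat")] <- 1
  }
  rownames(tab) <- NULL
  r2 <- if (degenerate) 0 else ss_model / ss_ctotal
  structure(list(
    table = tab,
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / df_err,
    mse = mse,
    df_error = df_err,
    data = dat
  ), class = "sban_anova")
}

#' @export
print.sban_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type III, balanced)\n")
  tab <- x$table
  tab$p <- format_p(tab$p)
  print(tab, row.names = FALSE)
  cat(sprintf("R squared = %.3f (Adjusted R squared = %.3f)\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

# SPSS-style p display: values below .0005 print as ".000"
format_p <- function(p) {
  ifelse(is.na(p), "", sub("^0", "", sprintf("%.3f", p)))
}

#' Write an ANOVA table as CSV
#'
#' Mirrors the reference column order (Source, SS, df, MS, F, p); p-values
#' below .0005 are rendered as `.000`.
#'
#' @param fit An `sban_anova`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_anova_table <- function(fit, path) {
  tab <- fit$table
  out <- data.frame(Source = tab$source, SS = tab$ss, df = tab$df,
                    MS = tab$ms, F = tab$f, p = format_p(tab$p),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Fisher's LSD pairwise comparisons
#'
#' Unadjusted pairwise t tests of factor marginal means using the error mean
#' square and error degrees of freedom of the full two-way model:
#' `SE = sqrt(MSE * (1/m_i + 1/m_j))` with `m` the marginal cell counts,
#' two-sided p from the t distribution on the error df.
#'
#' @param table Response table from [build_response_table()].
#' @param factor `"habitat"` (default) or `"sites"` (regime).
#' @param alpha Significance level for the flag (default 0.05).
#' @param force Run even when the omnibus F for the factor is not
#'   significant at `alpha` (default `FALSE`, matching post hoc practice).
#' @return data.frame `level_i`, `level_j`, `mean_diff`, `se`, `t`, `p`,
#'   `significant`.
#' @export
lsd_pairwise <- function(table, factor = c("habitat", "sites"),
                         alpha = 0.05, force = FALSE) {
  factor <- match.arg(factor)
  col <- if (factor == "habitat") "habitat" else "regime"
  levels <- sort(unique(table[[col]]))
  if (length(levels) < 2) {
    stop("factor ", factor, " has fewer than 2 levels", call. = FALSE)
  }
  fit <- anova_two_way(table)
  omnibus_p <- fit$table$p[fit$table$source ==
                             if (factor == "habitat") "habitat" else "sites"]
  if (!force && !is.na(omnibus_p) && omnibus_p >= alpha) {
    stop("omnibus ANOVA for ", factor, " not significant (p = ",
         sprintf("%.3f", omnibus_p), "); use force = TRUE to override",
         call. = FALSE)
  }
  means <- tapply(table$value, table[[col]], mean)
  m <- tapply(table$value, table[[col]], length)
  pairs <- utils::combn(levels, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(fit$mse * (1 / m[[i]] + 1 / m[[j]]))
    tval <- diff / se
    p <- 2 * stats::pt(-abs(tval), fit$df_error)
    data.frame(level_i = i, level_j = j, mean_diff = diff, se = se,
               t = tval, p = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
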
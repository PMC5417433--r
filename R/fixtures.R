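#' Packaged summary tables from the staged colonization assays
#'
#' Loads the summary statistics that ship with the package: per-species tree
#' diameter (DBH) and phloem-thickness means/SEs for 2013 and 2014 (n = 4
#' trees per species per year) with the published omnibus F footer;
#' per-species cumulative bark-entry percentages with asymmetric 95% CIs at
#' 24/48/72 h; and the pooled stage counts (bark entry 532/840, phloem entry
#' 84.7% of 1123, brood establishment 70.2% of 840 galleries). These are the
#' inputs to the summary-statistics ANOVA reconstruction and the pooled-stage
#' susceptibility product.
#'
#' @return a list with elements
#'   \item{table1}{data.frame: year, species, dbh/phloem means and SEs, n}
#'   \item{table1_footer}{data.frame of the omnibus F, dfs and P per column}
#'   \item{table2}{data.frame: species, host_class, hours, mean\%, 95\% CI,
#'     letter}
#'   \item{pooled}{named list of pooled stage counts
#'     (`exp1_pooled`, `exp2_pooled`, `exp3_pooled`), each with `stage`,
#'     `successes`, `total`, `percent`}
#' @examples
#' fx <- fixture_tables()
#' fx$pooled$exp1_pooled$successes  # 532
#' @export
fixture_tables <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "hostcol")
    if (!nzchar(p) || !file.exists(p)) stop("packaged fixture missing: ", f)
    p
  }
  t1 <- utils::read.csv(path("table1_trees.csv"), stringsAsFactors = FALSE)
  t1f <- utils::read.csv(path("table1_footer.csv"), stringsAsFactors = FALSE)
  t2 <- utils::read.csv(path("table2_bark_entry.csv"),
                        stringsAsFactors = FALSE)
  pooled <- jsonlite::read_json(path("pooled_stages.json"),
                                simplifyVector = TRUE)
  if (!all(c("exp1_pooled", "exp2_pooled", "exp3_pooled") %in% names(pooled)))
    stop("pooled_stages.json is corrupted")
  list(table1 = t1, table1_footer = t1f, table2 = t2, pooled = pooled)
}
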
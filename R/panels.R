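#' Built-in curated functional gene panels
#'
#' Three panels cover the functional domains of interest in enteropathy:
#' \describe{
#'   \item{slc}{solute carriers, matched by the "SLC" symbol prefix;}
#'   \item{xenobiotic}{xenobiotic-metabolizing enzyme families, matched by the
#'     prefixes CYP, UGT, GST, SULT, ADH, ALDH, FMO, NAT, EPHX;}
#'   \item{brush_border}{the 21 digestive-enzyme genes of the packaged
#'     reference table (see [table2_fixture()]), matched as an explicit
#'     symbol list.}
#' }
#' Prefix panels are a heuristic; supply an explicit collection via
#' [read_gmt()] for curated membership.
#'
#' @param name One of "slc", "xenobiotic", "brush_border".
#' @return A list with `name`, `member_genes` (character, possibly empty),
#'   `symbol_prefixes` (character, possibly empty), `description`. Exactly
#'   one of `member_genes` / `symbol_prefixes` is non-empty.
#' @export
builtin_panel <- function(name) {
  panels <- list(
    slc = list(name = "slc", member_genes = character(0),
               symbol_prefixes = "SLC",
               description = "Solute carrier membrane transporters (SLC superfamily)"),
    xenobiotic = list(name = "xenobiotic", member_genes = character(0),
                      symbol_prefixes = c("CYP", "UGT", "GST", "SULT", "ADH",
                                          "ALDH", "FMO", "NAT", "EPHX"),
                      description = "Xenobiotic-metabolizing enzyme families"),
    brush_border = list(name = "brush_border",
                        member_genes = table2_fixture()$gene_id,
                        symbol_prefixes = character(0),
                        description = "Digestive / brush-border enzyme genes from the packaged reference table")
  )
  if (!name %in% names(panels))
    stop("unknown panel '", name, "'; valid names: ",
         paste(names(panels), collapse = ", "))
  panels[[name]]
}

#' Packaged digestive-enzyme reference means
#'
#' The printed cohort mean FPKM for the 21 digestive-enzyme genes (pancreatic
#' proteases, brush-border proteases and disaccharidases, gastric lipase),
#' e.g. lactase LCT = (stunting 363.1, SAM 87.7, adult 14.0). These are
#' frozen constants shipped as a plain TSV; a checksum test guards them.
#'
#' @return A group-summary data.frame (as from [group_means()]): `gene_id`,
#'   `mean_stunting`, `mean_SAM`, `mean_adult`, `n_stunting`, `n_SAM`,
#'   `n_adult`, plus annotation columns `location`, `enzyme`, `ec_number`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_digestive_enzymes.tsv",
                      package = "enteroDEG", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  data.frame(gene_id = df$gene_id,
             mean_stunting = df$mean_stunting,
             mean_SAM = df$mean_SAM,
             mean_adult = df$mean_adult,
             n_stunting = 30L, n_SAM = 27L, n_adult = 37L,
             location = df$location, enzyme = df$enzyme,
             ec_number = df$ec_number, stringsAsFactors = FALSE)
}

# match a panel definition against gene ids (case-insensitive HGNC-style)
panel_match <- function(panel, gene_ids) {
  up <- toupper(gene_ids)
  if (length(panel$member_genes)) {
    gene_ids[up %in% toupper(panel$member_genes)]
  } else {
    hit <- rep(FALSE, length(up))
    for (pre in panel$symbol_prefixes) hit <- hit | startsWith(up, toupper(pre))
    gene_ids[hit]
  }
}

#' Panel-restricted ratio report
#'
#' Restricts a pairwise ratio comparison to a functional panel and applies
#' the display rule used for the panel dot plots: a gene is display-eligible
#' when its ratio lies outside the empirical 95% confidence limits
#' (`tail != "none"`) and both group means exceed 1 FPKM.
#'
#' @param summaries Group-mean data.frame (context only; gene universe).
#' @param records Ratio records after [tail_select()].
#' @param panel Panel definition from [builtin_panel()] or an equivalent
#'   list.
#' @return A data.frame sorted by log2 ratio: `gene_id`, `num_mean`,
#'   `den_mean`, `ratio`, `log2_ratio`, `tail`, `both_above_1`,
#'   `display_eligible`. Panel genes absent from the records are omitted;
#'   an empty match raises a warning and returns a zero-row report.
#' @export
panel_report <- function(summaries, records, panel) {
  matched <- panel_match(panel, records$gene_id)
  if (!length(matched))
    warning("panel '", panel$name, "' matched no genes in the comparison")
  rows <- records[records$gene_id %in% matched, , drop = FALSE]
  both_above_1 <- pmin(rows$num_mean, rows$den_mean) > 1
  out <- data.frame(gene_id = rows$gene_id,
                    num_mean = rows$num_mean,
                    den_mean = rows$den_mean,
                    ratio = rows$ratio,
                    log2_ratio = rows$log2_ratio,
                    tail = rows$tail,
                    both_above_1 = both_above_1,
                    display_eligible = rows$tail != "none" & both_above_1,
                    stringsAsFactors = FALSE)
  out[order(out$log2_ratio), , drop = FALSE]
}

#' Dot-plot of a panel report
#'
#' Plain base-graphics dot chart of log2 ratios for the display-eligible
#' genes of a panel report (or all matched genes when `eligible_only` is
#' FALSE).
#'
#' @param report Data.frame from [panel_report()].
#' @param eligible_only Restrict to display-eligible genes (default TRUE).
#' @param ... Passed to [graphics::dotchart()].
#' @export
plot_panel_report <- function(report, eligible_only = TRUE, ...) {
  rows <- if (eligible_only) report[report$display_eligible, , drop = FALSE] else report
  if (!nrow(rows)) {
    warning("nothing to plot")
    return(invisible(NULL))
  }
  graphics::dotchart(rows$log2_ratio, labels = rows$gene_id,
                     xlab = "log2 ratio", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(rows)
}
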
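# The interaction-site registry: named clusters of basic residues on the
# tubulin body that the acidic alpha-tail residues form salt bridges with.
# Sites 1 and 2 live on the beta-tubulin of the adjacent dimer toward the
# minus end of the same protofilament (trans); sites 3 and 4 are on the
# alpha-tubulin bearing the tail itself (cis).

#' Default interaction-site registry
#'
#' Four sites, in alpha/beta-tubulin author numbering:
#' site 1 (trans, adjacent beta): R390, R391, K392;
#' site 2 (trans, adjacent beta): K174, R213, R306, K379, R380;
#' site 3 (cis, own alpha): R308, K311, K338, R339;
#' site 4 (cis, own alpha): K112, R123, R156, K163, K430.
#'
#' @return a `site_registry` data frame with columns `site_id`, `host`
#'   (`"trans_beta_minus"` or `"cis_alpha"`), `resno`, `resname`.
#' @export
default_site_registry <- function() {
  reg <- rbind(
    data.frame(site_id = 1L, host = "trans_beta_minus",
               resno = c(390L, 391L, 392L),
               resname = c("ARG", "ARG", "LYS")),
    data.frame(site_id = 2L, host = "trans_beta_minus",
               resno = c(174L, 213L, 306L, 379L, 380L),
               resname = c("LYS", "ARG", "ARG", "LYS", "ARG")),
    data.frame(site_id = 3L, host = "cis_alpha",
               resno = c(308L, 311L, 338L, 339L),
               resname = c("ARG", "LYS", "LYS", "ARG")),
    data.frame(site_id = 4L, host = "cis_alpha",
               resno = c(112L, 123L, 156L, 163L, 430L),
               resname = c("LYS", "ARG", "ARG", "LYS", "LYS")))
  site_registry(reg)
}

#' Construct/validate a site registry
#'
#' @param df data frame with columns `site_id` (integer), `host`
#'   (`"trans_beta_minus"` or `"cis_alpha"`), `resno`, `resname` (LYS or
#'   ARG only).
#' @return the validated `site_registry`.
#' @export
site_registry <- function(df) {
  df <- as.data.frame(df)
  need <- c("site_id", "host", "resno", "resname")
  if (!all(need %in% names(df)))
    stop("site registry needs columns: ", paste(need, collapse = ", "))
  if (!all(df$resname %in% c("LYS", "ARG")))
    stop("site residues must be LYS or ARG")
  if (!all(df$host %in% c("trans_beta_minus", "cis_alpha")))
    stop("site host must be 'trans_beta_minus' or 'cis_alpha'")
  hosts <- unique(df[, c("site_id", "host")])
  if (anyDuplicated(hosts$site_id))
    stop("each site_id must have a single host relation")
  key <- paste(df$host, df$resno)
  if (anyDuplicated(key))
    stop("duplicate residue within a host: ", key[anyDuplicated(key)])
  df <- df[order(df$site_id, df$resno), need]
  rownames(df) <- NULL
  class(df) <- c("site_registry", "data.frame")
  df
}

#' Read a site registry from a TSV file
#' @param path tab-separated file with the [site_registry()] columns.
#' @return a `site_registry`.
#' @export
read_site_registry <- function(path) {
  site_registry(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a site registry to a TSV file
#' @param registry a `site_registry`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_site_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
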
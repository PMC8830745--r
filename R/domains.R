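# ABCA1 domain table: the six functional domains of the 2261-residue
# transporter. Residue stretches 1148-1326 and 2144-2261 belong to no listed
# domain and map to "unassigned" (they are linker/regulatory regions).

#' Default ABCA1 domain table
#'
#' Six domains of the ABCA1 lipid exporter: two extracellular domains (ECD),
#' two transmembrane domains (TMD, discontiguous in sequence) and two
#' nucleotide-binding domains (NBD).
#'
#' @return data.frame with columns \code{domain}, \code{start}, \code{end},
#'   \code{color}; one row per contiguous residue range, ranges non-overlapping.
#' @export
abca1_domains <- function() {
  data.frame(
    domain = c("TMD1", "ECD1", "TMD1", "NBD1", "TMD2", "ECD2", "TMD2", "NBD2"),
    start = c(1L, 46L, 631L, 903L, 1327L, 1366L, 1641L, 1907L),
    end = c(45L, 630L, 902L, 1147L, 1365L, 1640L, 1906L, 2143L),
    color = c("blue", "cyan", "blue", "yellow", "lime", "orange", "lime", "magenta"),
    stringsAsFactors = FALSE
  )
}

#' Validate a domain table
#' @param table data.frame with \code{domain}, \code{start}, \code{end}.
#' @return the table, invisibly; errors on overlap or inverted ranges.
#' @export
validate_domains <- function(table) {
  stopifnot(all(c("domain", "start", "end") %in% names(table)))
  if (any(table$end < table$start)) stopf("domain range with end < start")
  o <- order(table$start)
  s <- table$start[o]; e <- table$end[o]
  if (nrow(table) > 1 && any(s[-1] <= e[-nrow(table)]))
    stopf("domain ranges overlap")
  invisible(table)
}

#' Assign residues to domains
#'
#' @param resid integer vector of 1-based residue ids.
#' @param table domain table (default \code{\link{abca1_domains}()}); first
#'   matching range wins.
#' @return character vector of domain labels; \code{"unassigned"} where no
#'   range matches.
#' @export
assign_domain <- function(resid, table = abca1_domains()) {
  if (any(resid < 1)) stopf("residue ids must be >= 1")
  validate_domains(table)
  out <- rep("unassigned", length(resid))
  for (j in seq_len(nrow(table))) {
    hit <- out == "unassigned" & resid >= table$start[j] & resid <= table$end[j]
    out[hit] <- table$domain[j]
  }
  out
}
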
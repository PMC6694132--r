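#' The 23-trait cognitive assessment registry
#'
#' Names of the longitudinal cognitive traits assessed in the modelled
#' late-onset Alzheimer's disease cohort. Each trait yields two derived
#' phenotypes (latest value and per-year slope), so the registry drives 46
#' derived epistasis phenotype data sets.
#'
#' @return character vector of 23 trait abbreviations.
#' @export
henaTraits <- function() {
  c("ADAS11", "ADAD13", "CDRSB",
    "Ecog_PtDivatt", "Ecog_PtLang", "Ecog_PtMem", "Ecog_PtOrgan",
    "Ecog_PtPlan", "Ecog_PtVisspat", "Ecog_PtTotal",
    "Ecog_SPDivatt", "Ecog_SPLang", "Ecog_SPMem", "Ecog_SPOrgan",
    "Ecog_SPPlan", "Ecog_SPVisspat", "Ecog_SPTotal",
    "FAQ", "MOCA", "MMSE",
    "RAVLT_Immediate", "RAVLT_Learning", "RAVLT_Forgetting")
}

#' Default brain-region ontology
#'
#' Region identifiers used for the brain-region expression attributes: the
#' seven Alzheimer-affected regions of the hippocampal circuit (cornu
#' ammonis sectors CA1-CA4, dentate gyrus DG, subiculum, septal nuclei
#' SptN) followed by generic region codes up to the configured total.
#'
#' @param n total number of regions (default 231).
#' @return character vector of region identifiers, disease regions first.
#' @export
henaRegions <- function(n = 231) {
  dis <- henaDiseaseRegions()
  if (n < length(dis)) stop("need at least ", length(dis), " regions")
  c(dis, sprintf("R%03d", seq(length(dis) + 1, length.out = n - length(dis))))
}

#' @describeIn henaRegions the seven disease-associated region identifiers
#' @export
henaDiseaseRegions <- function() {
  c("CA1", "CA2", "CA3", "CA4", "DG", "subiculum", "SptN")
}

#' Packaged data-set registry
#'
#' Enumerates the 64 constituent data sets of the integrated network and
#' their six data types: one cross-study co-expression set (ADN), seven
#' region co-expression sets (ABA_CA1..ABA_SptN), three cohort epistasis
#' sets (ADNI_VER, TGEN, HBTRC), 46 cognitive-trait epistasis sets
#' (ADNI_CT_<trait>_<latest|slope>), four PPI sets (PBA, IAH, ADIA, SIA),
#' one GWAS set, one positive-selection set and one aggregated brain-region
#' expression set (ABA).
#'
#' @return \code{data.frame} with columns \code{data_source_id},
#'   \code{data_type}, \code{data_source_name}.
#' @export
henaDatasetRegistry <- function() {
  ct <- as.vector(outer(henaTraits(), c("latest", "slope"),
                        function(tr, d) paste("ADNI_CT", tr, d, sep = "_")))
  reg <- rbind(
    data.frame(data_source_id = "ADN", data_type = "co-expression",
               data_source_name = "Cross-study co-expression, AD and healthy brain"),
    data.frame(data_source_id = paste0("ABA_", henaDiseaseRegions()),
               data_type = "co-expression",
               data_source_name = paste("Co-expression in", henaDiseaseRegions(),
                                        "brain region")),
    data.frame(data_source_id = c("ADNI_VER", "TGEN", "HBTRC"),
               data_type = "epistasis",
               data_source_name = c("Epistasis, ventricular volume change (ADNI)",
                                    "Epistasis, Braak score (TGEN)",
                                    "Epistasis, Braak score (HBTRC)")),
    data.frame(data_source_id = sort(ct), data_type = "epistasis",
               data_source_name = paste("Epistasis, cognitive trait", sort(ct))),
    data.frame(data_source_id = c("PBA", "IAH", "ADIA", "SIA"),
               data_type = "PPI",
               data_source_name = c("PPI in brain ageing (yeast two-hybrid)",
                                    "PPI from IntAct in human",
                                    "Alzheimer's disease PPI from IntAct",
                                    "Synaptic PPI from IntAct")),
    data.frame(data_source_id = "GWAS", data_type = "GWAS",
               data_source_name = "LOAD GWAS meta-analysis SNP associations"),
    data.frame(data_source_id = "PS", data_type = "positive selection",
               data_source_name = "Positive Darwinian selection p-values"),
    data.frame(data_source_id = "ABA", data_type = "gene expression",
               data_source_name = "Aggregated expression in 231 brain regions"))
  rownames(reg) <- NULL
  reg
}
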
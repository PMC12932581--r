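#' Default 166-region atlas labels
#'
#' Returns an ordered character vector of region labels used to name ROI
#' feature columns. The default list follows the naming style of a 166-region
#' whole-brain parcellation (bilateral cortical and cerebellar regions, vermis
#' lobules, thalamic nuclei and brainstem nuclei). Any user-supplied ordered
#' label list of matching length can be used instead; nothing downstream
#' depends on the anatomical content of the labels.
#'
#' @param n Number of regions. For `n != 166` generic `ROI_###` labels are
#'   returned.
#' @return Character vector of length `n` with unique labels.
#' @export
#' @examples
#' head(atlas_labels())
atlas_labels <- function(n = 166L) {
  n <- as.integer(n)
  if (n != 166L) {
    return(sprintf("ROI_%03d", seq_len(n)))
  }
  bilateral <- c(
    "Precentral", "Frontal.Sup", "Frontal.Mid", "Frontal.Inf.Oper",
    "Frontal.Inf.Tri", "Frontal.Inf.Orb", "Rolandic.Oper", "Supp.Motor.Area",
    "Olfactory", "Frontal.Sup.Medial", "Frontal.Med.Orb", "Rectus",
    "OFCmed", "OFCant", "OFCpost", "OFClat", "Insula",
    "ACC.Sub", "ACC.Pre", "ACC.Sup", "Cingulate.Mid", "Cingulate.Post",
    "Hippocampus", "ParaHippocampal", "Amygdala",
    "Calcarine", "Cuneus", "Lingual",
    "Occipital.Sup", "Occipital.Mid", "Occipital.Inf", "Fusiform",
    "Postcentral", "Parietal.Sup", "Parietal.Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral.Lobule",
    "Caudate", "Putamen", "Pallidum", "Heschl",
    "Temporal.Sup", "Temporal.Pole.Sup", "Temporal.Mid", "Temporal.Pole.Mid",
    "Temporal.Inf"
  )
  cerebellum <- c(
    "Cerebellum.Crus1", "Cerebellum.Crus2", "Cerebellum.3", "Cerebellum.4.5",
    "Cerebellum.6", "Cerebellum.7b", "Cerebellum.8", "Cerebellum.9",
    "Cerebellum.10"
  )
  vermis <- c(
    "Vermis.1.2", "Vermis.3", "Vermis.4.5", "Vermis.6", "Vermis.7",
    "Vermis.8", "Vermis.9"
  )
  thalamus <- c(
    "Thal.AV", "Thal.LP", "Thal.VA", "Thal.VL", "Thal.VPL", "Thal.IL",
    "Thal.Re", "Thal.MDm", "Thal.MDl", "Thal.LGN", "Thal.MGN",
    "Thal.PuA", "Thal.PuM", "Thal.PuL", "Thal.PuI"
  )
  nuclei <- c("N.Acc", "VTA", "SN.pc", "SN.pr", "Red.N", "LC")
  midline <- c("Vermis.10", "Raphe.D", "Raphe.M")
  lr <- function(x) as.vector(t(outer(x, c("L", "R"), paste, sep = ".")))
  labels <- c(lr(bilateral), lr(cerebellum), vermis, lr(thalamus),
              lr(nuclei), midline)
  stopifnot(length(labels) == 166L, !anyDuplicated(labels))
  labels
}
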
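#' Reference per-cause confusion counts from a hospital autopsy series
#'
#' Per-cause classification counts (TP/TN/FP/FN) and the corresponding
#' published integer percentages from a 316-death hospital-based validation
#' of an InterVA-style coder against complete diagnostic autopsy: one block
#' per study group at the broad-category level (`table = "broad"`), plus the
#' pooled 192 deaths from infectious causes re-analysed at the
#' infection-subtype level (`table = "infection"`). The percentage columns
#' are the printed display values (round half to even); `NA` marks entries
#' that are not applicable (zero denominator).
#'
#' These rows serve as worked examples for [binary_metrics()]: recomputing
#' the four percentages from the counts reproduces every printed value.
#'
#' @return data.frame with columns `table`, `group`, `cause`, `n`, `TP`,
#'   `TN`, `FP`, `FN`, `sensitivity_pct`, `specificity_pct`, `ppv_pct`,
#'   `npv_pct`.
#' @export
#' @examples
#' ref <- reference_confusion_counts()
#' m <- binary_metrics(ref)
#' all(m$sensitivity_pct == ref$sensitivity_pct, na.rm = TRUE)
reference_confusion_counts <- function() {
  txt <- "table,group,cause,n,TP,TN,FP,FN,sensitivity_pct,specificity_pct,ppv_pct,npv_pct
broad,stillbirth,infections,4,0,14,0,4,0,100,NA,78
broad,stillbirth,fetal_growth_restriction,7,0,10,1,7,0,91,0,59
broad,stillbirth,intrapartum_hypoxia,3,0,15,0,3,0,100,NA,83
broad,stillbirth,intrauterine_hypoxia,2,0,16,0,2,0,100,NA,89
broad,stillbirth,congenital_malformations,0,0,11,7,0,NA,61,0,100
broad,stillbirth,non_conclusive,2,1,7,9,1,50,44,10,88
broad,neonate,infections,27,25,2,12,2,93,14,68,50
broad,neonate,congenital_malformations,4,1,37,0,3,25,100,100,92
broad,neonate,preterm_complications,5,0,36,0,5,0,100,NA,88
broad,neonate,intrapartum_complications,3,1,36,2,2,33,95,33,95
broad,neonate,other_diseases,2,0,39,0,2,0,100,NA,95
broad,neonate,non_conclusive,0,0,41,0,0,NA,100,NA,100
broad,child,infections,42,35,3,9,7,83,25,80,30
broad,child,congenital_malformations,2,0,52,0,2,0,100,NA,96
broad,child,malignant_neoplasms,7,0,47,0,7,0,100,NA,87
broad,child,other_diseases,3,0,44,7,3,0,86,0,94
broad,child,non_conclusive,0,0,51,3,0,NA,94,0,100
broad,maternal,infections,39,11,39,13,28,28,75,46,58
broad,maternal,abortion,9,0,82,0,9,0,100,NA,90
broad,maternal,eclampsia,4,3,64,23,1,75,74,12,98
broad,maternal,obstetric_hemorrhage,16,12,59,16,4,75,79,43,94
broad,maternal,other_obstetric_complications,6,0,85,0,6,0,100,NA,93
broad,maternal,non_obstetric_diseases,16,4,67,8,12,25,89,33,85
broad,maternal,non_conclusive,1,0,89,1,1,0,99,0,99
broad,other_adult,infections,80,54,20,12,26,68,62,82,43
broad,other_adult,malignant_neoplasms,16,3,95,1,13,19,99,75,88
broad,other_adult,other_diseases,16,10,66,30,6,62,69,25,92
broad,other_adult,non_conclusive,0,0,110,2,0,NA,98,0,100
infection,NA,disseminated_infections,51,0,139,2,51,0,99,0,73
infection,NA,pneumonia,36,13,102,54,23,36,65,19,82
infection,NA,meningitis,15,3,173,4,12,20,98,43,94
infection,NA,tuberculosis,7,0,183,2,7,0,99,0,96
infection,NA,diarrhoea,2,0,186,4,2,0,98,0,99
infection,NA,hiv_aids_related,57,18,120,15,39,32,89,55,75
infection,NA,malaria,6,2,181,5,4,33,97,29,98
infection,NA,other_infections,18,0,171,3,18,0,98,0,90"
  utils::read.csv(text = txt, stringsAsFactors = FALSE,
                  colClasses = c(rep("character", 3), rep("integer", 9)))
}
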
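# Bundled mini-terminologies for simulation and examples. These are small
# synthetic excerpts shaped like MedDRA/ATC, not licensed content: just
# enough vocabulary for a migraine-drug safety study (vasospastic events,
# common co-reported terms, CGRP antagonists, triptans, beta-blockers).

#' Bundled PT/HLT/SOC table for the migraine-drug safety domain
#'
#' A small synthetic MedDRA-style excerpt. "Raynaud's phenomenon" and
#' "Peripheral coldness" sit under the HLT "Peripheral vasoconstriction,
#' necrosis and vascular insufficiency"; common co-reported terms sit under
#' generic HLTs of their organ class.
#'
#' @return A tibble with columns `pt`, `hlt`, `soc`.
#' @export
migraine_term_table <- function() {
  vasc_hlt <- "Peripheral vasoconstriction, necrosis and vascular insufficiency"
  vasc_soc <- "Vascular disorders"
  tibble(
    pt = c(
      "Raynaud's phenomenon", "Peripheral coldness", "Extremity necrosis",
      "Gangrene", "Peripheral ischaemia",
      "Headache", "Migraine", "Dizziness",
      "Arthralgia", "Myalgia",
      "Alopecia", "Skin discolouration", "Rash",
      "Condition aggravated", "Fatigue", "Injection site reaction",
      "Constipation", "Nausea", "Diarrhoea",
      "Weight increased"
    ),
    hlt = c(
      vasc_hlt, vasc_hlt, vasc_hlt, vasc_hlt, vasc_hlt,
      "Headaches NEC", "Migraine headaches", "Neurological signs NEC",
      "Joint related signs and symptoms", "Muscle pains",
      "Alopecias", "Pigmentation changes", "Rashes NEC",
      "General signs and symptoms NEC", "Asthenic conditions",
      "Injection site reactions",
      "Gastrointestinal motility disorders", "Nausea and vomiting symptoms",
      "Diarrhoea symptoms",
      "Weight gain"
    ),
    soc = c(
      vasc_soc, vasc_soc, vasc_soc, vasc_soc, vasc_soc,
      "Nervous system disorders", "Nervous system disorders",
      "Nervous system disorders",
      "Musculoskeletal disorders", "Musculoskeletal disorders",
      "Skin disorders", "Skin disorders", "Skin disorders",
      "General disorders", "General disorders", "General disorders",
      "Gastrointestinal disorders", "Gastrointestinal disorders",
      "Gastrointestinal disorders",
      "Investigations"
    )
  )
}

#' Bundled ingredient/ATC table for the migraine-drug safety domain
#'
#' Covers the ten CGRP-targeting ingredients of the N02CD class, the seven
#' marketed triptans (N02CC), and the five beta-blockers used in migraine
#' prophylaxis. Development-stage CGRP antagonists without a published ATC
#' code (olcegepant, telcagepant, vazegepant) carry synthetic `N02CD9x`
#' placeholders so the class prefix query covers the whole class.
#'
#' @return A tibble with columns `ingredient`, `atc_code`.
#' @export
migraine_drug_table <- function() {
  tibble(
    ingredient = c(
      "erenumab", "galcanezumab", "fremanezumab", "eptinezumab",
      "ubrogepant", "rimegepant", "atogepant",
      "olcegepant", "telcagepant", "vazegepant",
      "sumatriptan", "naratriptan", "zolmitriptan", "rizatriptan",
      "almotriptan", "eletriptan", "frovatriptan",
      "propranolol", "timolol", "nadolol", "metoprolol", "atenolol",
      "amitriptyline", "topiramate", "paracetamol", "ibuprofen"
    ),
    atc_code = c(
      "N02CD01", "N02CD02", "N02CD03", "N02CD05",
      "N02CD04", "N02CD06", "N02CD07",
      "N02CD90", "N02CD91", "N02CD92",
      "N02CC01", "N02CC02", "N02CC03", "N02CC04",
      "N02CC05", "N02CC06", "N02CC07",
      "C07AA05", "C07AA06", "C07AA12", "C07AB02", "C07AB03",
      "N06AA09", "N03AX11", "N02BE01", "M01AE01"
    )
  )
}
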
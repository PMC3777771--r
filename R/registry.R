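#' The 78-region cortical atlas registry
#'
#' Ordered AAL cortical labels with explicit `_L`/`_R` hemisphere suffixes:
#' the 90 cerebral AAL regions minus the twelve subcortical ones
#' (hippocampus, amygdala, caudate, putamen, pallidum, thalamus,
#' bilaterally), leaving exactly 78 cortical regions of interest.
#'
#' @return Character vector of 78 unique labels.
#' @export
#' @examples
#' length(roi_registry())
roi_registry <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "ParaHippocampal",
    "Calcarine", "Cuneus", "Lingual", "Occipital_Sup", "Occipital_Mid",
    "Occipital_Inf", "Fusiform", "Postcentral", "Parietal_Sup",
    "Parietal_Inf", "SupraMarginal", "Angular", "Precuneus",
    "Paracentral_Lobule", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(t(outer(base, c("_L", "_R"), paste0)))
}

#' Default resting-state network definitions
#'
#' Literature-based memberships for the four networks analysed by the
#' pipeline: the default mode network (DMN: medial prefrontal, anterior and
#' posterior cingulate, precuneus, bilateral inferior parietal and medial
#' temporal regions), hemisphere-specific left/right frontoparietal networks
#' (dorsolateral prefrontal plus parietal regions), and the executive control
#' network (frontal plus cingulate regions). Memberships follow published
#' anatomical descriptions mapped onto atlas labels and are intentionally
#' data, not code: alternative definitions are supplied via
#' [load_rsn_config()].
#'
#' @return Named list of character vectors of registry labels.
#' @export
default_rsns <- function() {
  list(
    DMN = c("Frontal_Sup_Medial_L", "Frontal_Sup_Medial_R",
            "Frontal_Med_Orb_L", "Frontal_Med_Orb_R",
            "Cingulum_Ant_L", "Cingulum_Ant_R",
            "Cingulum_Post_L", "Cingulum_Post_R",
            "Precuneus_L", "Precuneus_R",
            "Parietal_Inf_L", "Parietal_Inf_R",
            "Angular_L", "Angular_R",
            "ParaHippocampal_L", "ParaHippocampal_R"),
    FPN_left = c("Frontal_Sup_L", "Frontal_Mid_L", "Frontal_Inf_Tri_L",
                 "Parietal_Sup_L", "Parietal_Inf_L", "SupraMarginal_L",
                 "Angular_L"),
    FPN_right = c("Frontal_Sup_R", "Frontal_Mid_R", "Frontal_Inf_Tri_R",
                  "Parietal_Sup_R", "Parietal_Inf_R", "SupraMarginal_R",
                  "Angular_R"),
    ECN = c("Frontal_Sup_L", "Frontal_Sup_R", "Frontal_Mid_L",
            "Frontal_Mid_R", "Cingulum_Ant_L", "Cingulum_Ant_R",
            "Cingulum_Mid_L", "Cingulum_Mid_R",
            "Supp_Motor_Area_L", "Supp_Motor_Area_R")
  )
}

validate_rsns <- function(networks, registry, hemisphere_check = TRUE) {
  if (length(networks) == 0) abort("no networks defined")
  if (is.null(names(networks)) || any(names(networks) == "")) {
    abort("every network must be named")
  }
  if (anyDuplicated(names(networks))) {
    dup <- unique(names(networks)[duplicated(names(networks))])
    abort(sprintf("duplicate network name(s): %s", paste(dup, collapse = ", ")))
  }
  for (nm in names(networks)) {
    members <- networks[[nm]]
    if (length(members) < 2) {
      abort(sprintf("network '%s' must have at least 2 members (has %d)",
                    nm, length(members)))
    }
    if (anyDuplicated(members)) {
      abort(sprintf("network '%s' lists duplicate member(s): %s", nm,
                    paste(unique(members[duplicated(members)]), collapse = ", ")))
    }
    unknown <- setdiff(members, registry)
    if (length(unknown) > 0) {
      abort(sprintf("network '%s' references label(s) not in the registry: %s",
                    nm, paste(unknown, collapse = ", ")))
    }
    if (hemisphere_check && grepl("(_left|_Left)$", nm)) {
      if (!all(grepl("_L$", members))) {
        abort(sprintf("left-hemisphere network '%s' contains non-left labels", nm))
      }
    }
    if (hemisphere_check && grepl("(_right|_Right)$", nm)) {
      if (!all(grepl("_R$", members))) {
        abort(sprintf("right-hemisphere network '%s' contains non-right labels", nm))
      }
    }
  }
  invisible(networks)
}

#' Load an atlas registry and RSN definitions from a YAML config
#'
#' The file has an optional `registry:` list (defaults to the shipped 78-label
#' cortical registry) and a `networks:` mapping of network name to member
#' label list. Every membership is validated against the registry; unknown
#' labels are reported together with the offending network.
#'
#' @param path Path to a YAML file; defaults to the configuration shipped
#'   with the package.
#' @return List with elements `registry` (character) and `networks`
#'   (named list of character vectors).
#' @export
#' @examples
#' cfg <- load_rsn_config()
#' names(cfg$networks)
load_rsn_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rsn_default.yaml", package = "megrsn")
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  registry <- if (is.null(cfg$registry)) roi_registry() else as.character(cfg$registry)
  if (anyDuplicated(registry)) abort("registry labels must be unique")
  if (is.null(cfg$networks)) abort("config must define a 'networks:' mapping")
  networks <- lapply(cfg$networks, as.character)
  validate_rsns(networks, registry)
  list(registry = registry, networks = networks)
}
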
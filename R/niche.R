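# The BCSC niche model: 37 mass-action channels coupling two stem-cell
# states (proliferative epithelial MET-like, quiescent mesenchymal EMT-like)
# to cytokines (IL-6, IL-8, TGF-beta, BMP), receptors (gp130, CXCR1, HER2,
# EGFR, TGFbR2), and intracellular signals (Stat3, Akt, NF-kB held as the
# IkB.p50.RelA complex, Lin-28, Let-7, beta-catenin, mir-93, HER2 mRNA).
# Core motif: IL-6 binds gp130 and activates Stat3; active Stat3 (and active
# Akt, downstream of HER2.EGFR and IL-8.CXCR1) releases p50.RelA from IkB;
# free p50.RelA transcribes IL-6 (positive feedback) and Lin-28; Lin-28 and
# HER2.EGFR activate beta-catenin, which drives symmetric MET self-renewal.

#' Display names for niche species identifiers
#'
#' ASCII-normalized identifiers are used throughout the code; this table
#' maps them to the conventional display names.
#'
#' @return Data frame with columns `id`, `display`.
#' @export
niche_species_names <- function() {
  data.frame(
    id = c("MET", "EMT", "IL6", "IL8", "TGFb", "BMP",
           "gp130", "CXCR1", "HER2", "EGFR", "TGFbR2",
           "IL6_gp130", "IL8_CXCR1", "HER2_EGFR", "TGFb_TGFbR2",
           "Lin28_HER2_mRNA", "IkB_p50_RelA", "Let7_IL6", "Lin28_Let7",
           "mir93_TGFb",
           "Stat3", "act_Stat3", "Akt", "act_Akt", "IkB", "p50_RelA",
           "Lin28", "Let7", "bcat", "act_bcat", "mir93", "HER2_mRNA"),
    display = c("MET-like BCSC", "EMT-like BCSC", "IL-6", "IL-8",
                "TGF-β", "BMP",
                "gp130", "CXCR1", "HER2", "EGFR", "TGF-βR2",
                "IL-6·gp130", "IL-8·CXCR1", "HER2·EGFR",
                "TGF-β·TGF-βR2",
                "Lin-28·HER2 mRNA", "IκB·p50·RelA",
                "Let-7·IL-6", "Lin-28·Let-7",
                "mir93·TGF-β",
                "Stat3", "act Stat3", "Akt", "act Akt", "IκB",
                "p50·RelA", "Lin-28", "Let-7", "β-catenin",
                "act β-catenin", "mir-93", "HER2 mRNA"),
    stringsAsFactors = FALSE)
}

#' Default niche initial particle counts
#'
#' 800 epithelial and 200 mesenchymal BCSCs; IL-6 at 1000 (elevated relative
#' to the other cytokines); IL-8 and TGF-beta at 100; every receptor and
#' free signaling molecule at 100; all dimers, activated forms, free IkB and
#' p50-RelA, and Lin-28 at 0.
#'
#' @return Named numeric vector of counts.
#' @export
niche_initial_counts <- function() {
  c(MET = 800, EMT = 200,
    IL6 = 1000, IL8 = 100, TGFb = 100, BMP = 100,
    gp130 = 100, CXCR1 = 100, HER2 = 100, EGFR = 100, TGFbR2 = 100,
    IL6_gp130 = 0, IL8_CXCR1 = 0, HER2_EGFR = 0, TGFb_TGFbR2 = 0,
    Lin28_HER2_mRNA = 0, IkB_p50_RelA = 100, Let7_IL6 = 0, Lin28_Let7 = 0,
    mir93_TGFb = 0,
    Stat3 = 100, act_Stat3 = 0, Akt = 100, act_Akt = 0,
    IkB = 0, p50_RelA = 0, Lin28 = 0, Let7 = 100,
    bcat = 100, act_bcat = 0, mir93 = 100, HER2_mRNA = 100)
}

#' Default niche rate constants
#'
#' The published model does not print per-channel rate constants, so these
#' defaults follow the stated scale relations -- receptor binding and
#' dissociation on similar time scales, transcription about an order of
#' magnitude rarer, signaling in between -- and were then calibrated (via
#' the deterministic mean-field trajectory, procedure in the methods
#' vignette) so the model's documented qualitative behaviour holds under the
#' default initial counts. All values are overridable via [set_rates()] or
#' the `rates` argument of [build_niche_model()]. Units: day^-1 for
#' first-order channels, particle^-1 day^-1 for second-order ones.
#'
#' @return Named numeric vector keyed by reaction label.
#' @export
niche_rate_defaults <- function() {
  c(
    # receptor binding / dissociation (similar propensity scales at the
    # default counts; IL-6 binding is weaker per particle because IL-6 is
    # 10x more abundant). The reversible subsystems equilibrate within days
    # -- fast against the 1000-day cell dynamics -- and their equilibrium
    # ratios, not their kinetics, are what couple to the cells.
    IL6_gp130_binding = 2e-4, IL6_gp130_dissoc = 0.1,
    IL8_CXCR1_binding = 1e-3, IL8_CXCR1_dissoc = 0.1,
    TGFb_TGFbR2_binding = 1e-3, TGFb_TGFbR2_dissoc = 0.1,
    HER2_EGFR_binding = 1e-3, HER2_EGFR_dissoc = 0.1,
    # signal activation / deactivation; Stat3 and Akt activation is
    # receptor-complex driven, with gp130 and HER2.EGFR the strong routes
    # and IL-8.CXCR1 a weak auxiliary one
    Stat3_act_by_IL6_gp130 = 1e-3, Stat3_act_by_IL8_CXCR1 = 5e-6,
    Akt_act_by_IL8_CXCR1 = 5e-6, Akt_act_by_HER2_EGFR = 1e-3,
    Stat3_deact = 0.01, Akt_deact = 0.01,
    NFkB_act_by_Akt = 1e-3, NFkB_act_by_Stat3 = 1e-3,
    NFkB_IkB_rebinding = 0.01,
    bcat_act_by_Lin28 = 5e-4, bcat_act_by_HER2_EGFR = 1e-3,
    bcat_deact = 0.01,
    # microRNA / mRNA sequestration; the Lin-28 . HER2 mRNA complex has no
    # dissociation channel, so its binding constant is an absolute sink
    # rate balanced against Lin-28 transcription
    Lin28_HER2_mRNA_binding = 0.001,
    Lin28_Let7_binding = 1e-4, Lin28_Let7_dissoc = 0.01,
    Let7_IL6_binding = 1e-4, Let7_IL6_dissoc = 0.02,
    mir93_TGFb_binding = 1e-3, mir93_TGFb_dissoc = 0.1,
    # EMT/MET transitions (cell x regulator, particle^-1 day^-1); IL-6 is
    # the dominant EMT driver at the elevated default IL-6 level
    EMT_by_IL6_gp130 = 3e-4, EMT_by_TGFb = 1e-4,
    MET_by_mir93 = 1e-4, MET_by_BMP = 1e-4, MET_by_HER2_EGFR = 1e-4,
    # self-renewal and death of epithelial BCSCs
    MET_renewal = 4e-4, MET_death = 0.02,
    # transcription (rare; Lin-28 is the strongly NF-kB-responsive one)
    HER2_transcription = 0.001, IL6_transcription = 0.001,
    Lin28_transcription = 0.02
  )
}

.niche_species <- function(init) {
  cat_of <- c(MET = "cell", EMT = "cell",
              IL6 = "cytokine", IL8 = "cytokine", TGFb = "cytokine",
              BMP = "cytokine",
              gp130 = "receptor", CXCR1 = "receptor", HER2 = "receptor",
              EGFR = "receptor", TGFbR2 = "receptor",
              IL6_gp130 = "complex", IL8_CXCR1 = "complex",
              HER2_EGFR = "complex", TGFb_TGFbR2 = "complex",
              Lin28_HER2_mRNA = "complex", IkB_p50_RelA = "complex",
              Let7_IL6 = "complex", Lin28_Let7 = "complex",
              mir93_TGFb = "complex")
  lapply(names(init), function(nm) {
    species(nm,
            if (nm %in% names(cat_of)) cat_of[[nm]] else "intracellular-signal",
            init[[nm]])
  })
}

.niche_reactions <- function(rates) {
  r <- function(label, reactants, products, category) {
    reaction(label, reactants, products, rates[[label]], category)
  }
  list(
    r("IL6_gp130_binding", c("IL6", "gp130"), "IL6_gp130", "binding"),
    r("IL6_gp130_dissoc", "IL6_gp130", c("IL6", "gp130"), "dissociation"),
    r("IL8_CXCR1_binding", c("IL8", "CXCR1"), "IL8_CXCR1", "binding"),
    r("IL8_CXCR1_dissoc", "IL8_CXCR1", c("IL8", "CXCR1"), "dissociation"),
    r("TGFb_TGFbR2_binding", c("TGFb", "TGFbR2"), "TGFb_TGFbR2", "binding"),
    r("TGFb_TGFbR2_dissoc", "TGFb_TGFbR2", c("TGFb", "TGFbR2"),
      "dissociation"),
    r("HER2_EGFR_binding", c("HER2", "EGFR"), "HER2_EGFR", "binding"),
    r("HER2_EGFR_dissoc", "HER2_EGFR", c("HER2", "EGFR"), "dissociation"),
    r("Stat3_act_by_IL6_gp130", c("IL6_gp130", "Stat3"),
      c("IL6_gp130", "act_Stat3"), "signaling"),
    r("Akt_act_by_IL8_CXCR1", c("IL8_CXCR1", "Akt"),
      c("IL8_CXCR1", "act_Akt"), "signaling"),
    r("Stat3_act_by_IL8_CXCR1", c("IL8_CXCR1", "Stat3"),
      c("IL8_CXCR1", "act_Stat3"), "signaling"),
    r("Akt_act_by_HER2_EGFR", c("HER2_EGFR", "Akt"),
      c("HER2_EGFR", "act_Akt"), "signaling"),
    r("NFkB_act_by_Akt", c("act_Akt", "IkB_p50_RelA"),
      c("act_Akt", "IkB", "p50_RelA"), "signaling"),
    r("Akt_deact", "act_Akt", "Akt", "signaling"),
    r("NFkB_act_by_Stat3", c("act_Stat3", "IkB_p50_RelA"),
      c("act_Stat3", "IkB", "p50_RelA"), "signaling"),
    r("Stat3_deact", "act_Stat3", "Stat3", "signaling"),
    r("Lin28_HER2_mRNA_binding", c("Lin28", "HER2_mRNA"),
      "Lin28_HER2_mRNA", "binding"),
    r("bcat_act_by_Lin28", c("Lin28", "bcat"), c("Lin28", "act_bcat"),
      "signaling"),
    r("bcat_act_by_HER2_EGFR", c("HER2_EGFR", "bcat"),
      c("HER2_EGFR", "act_bcat"), "signaling"),
    r("bcat_deact", "act_bcat", "bcat", "signaling"),
    r("Lin28_Let7_binding", c("Lin28", "Let7"), "Lin28_Let7", "binding"),
    r("Lin28_Let7_dissoc", "Lin28_Let7", c("Lin28", "Let7"), "dissociation"),
    r("Let7_IL6_binding", c("Let7", "IL6"), "Let7_IL6", "binding"),
    r("Let7_IL6_dissoc", "Let7_IL6", c("Let7", "IL6"), "dissociation"),
    r("mir93_TGFb_binding", c("mir93", "TGFb"), "mir93_TGFb", "binding"),
    r("mir93_TGFb_dissoc", "mir93_TGFb", c("mir93", "TGFb"), "dissociation"),
    r("NFkB_IkB_rebinding", c("IkB", "p50_RelA"), "IkB_p50_RelA", "binding"),
    # free TGF-beta (not the receptor complex) drives the MET -> EMT channel,
    # exactly as the channel list prints it
    r("EMT_by_IL6_gp130", c("MET", "IL6_gp130"), c("EMT", "IL6_gp130"),
      "transition"),
    r("EMT_by_TGFb", c("MET", "TGFb"), c("EMT", "TGFb"), "transition"),
    r("MET_by_mir93", c("EMT", "mir93"), c("MET", "mir93"), "transition"),
    r("MET_by_BMP", c("EMT", "BMP"), c("MET", "BMP"), "transition"),
    r("MET_by_HER2_EGFR", c("EMT", "HER2_EGFR"), c("MET", "HER2_EGFR"),
      "transition"),
    r("MET_death", "MET", character(0), "death"),
    r("MET_renewal", c("MET", "act_bcat"), c("MET", "MET", "act_bcat"),
      "renewal"),
    r("HER2_transcription", "Lin28_HER2_mRNA",
      c("Lin28", "HER2", "HER2_mRNA"), "transcription"),
    r("IL6_transcription", "p50_RelA", c("IL6", "p50_RelA"),
      "transcription"),
    r("Lin28_transcription", "p50_RelA", c("p50_RelA", "Lin28"),
      "transcription")
  )
}

#' Build the BCSC niche reaction network
#'
#' Constructs the 37-channel niche model with the default (or overridden)
#' rate constants and initial counts.
#'
#' @param rates Named numeric vector of rate constants; entries override
#'   [niche_rate_defaults()]. A label outside the channel list is an error.
#' @param init Named numeric vector of initial counts; entries override
#'   [niche_initial_counts()].
#' @return A reaction network with 32 species and 37 channels.
#' @examples
#' net <- build_niche_model()
#' initial_state(net)[["MET"]]  # 800
#' @export
build_niche_model <- function(rates = NULL, init = NULL) {
  r0 <- niche_rate_defaults()
  if (!is.null(rates)) {
    unknown <- setdiff(names(rates), names(r0))
    if (length(unknown)) {
      stop("unknown niche reaction label: ", unknown[1L], call. = FALSE)
    }
    r0[names(rates)] <- rates
  }
  if (anyNA(r0)) {
    stop("missing rate constant for: ",
         paste(names(r0)[is.na(r0)], collapse = ", "), call. = FALSE)
  }
  i0 <- niche_initial_counts()
  if (!is.null(init)) {
    unknown <- setdiff(names(init), names(i0))
    if (length(unknown)) {
      stop("unknown niche species: ", unknown[1L], call. = FALSE)
    }
    i0[names(init)] <- init
  }
  build_network(.niche_species(i0), .niche_reactions(r0))
}

#' Default map from inhibitable niche elements to reaction channels
#'
#' The published screen inhibits nine niche elements singly and pairwise by
#' scaling reaction rate constants by 1e-10; it does not enumerate which
#' channels each inhibitor touches. This table is the package's documented,
#' user-editable convention: a ligand blockade scales its receptor-binding
#' channel, its production channel, and any transition channel driven by the
#' free ligand; a receptor blockade scales its dimerization and production;
#' a microRNA knockdown scales the channels in which the microRNA acts; a
#' signaling-node inhibitor scales the node's activation channels.
#'
#' @return Named list: target name -> character vector of reaction labels.
#' @export
niche_inhibition_map <- function() {
  list(
    IL6 = c("IL6_gp130_binding", "IL6_transcription"),
    IL8 = "IL8_CXCR1_binding",
    TGFb = c("TGFb_TGFbR2_binding", "EMT_by_TGFb"),
    BMP = "MET_by_BMP",
    mir93 = c("MET_by_mir93", "mir93_TGFb_binding"),
    HER2 = c("HER2_EGFR_binding", "HER2_transcription"),
    Akt = c("Akt_act_by_IL8_CXCR1", "Akt_act_by_HER2_EGFR"),
    Stat3 = c("Stat3_act_by_IL6_gp130", "Stat3_act_by_IL8_CXCR1"),
    Lin28 = c("Lin28_transcription", "bcat_act_by_Lin28")
  )
}
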
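# A synthetic stand-in for the licensed MedDRA dictionary: a small
# single-axial PT/HLT/HLGT/SOC tree with SMQs, IME/DME flags and
# product-quality terms. Term names echo the real grouping-term names used
# by the packaged historical-concern register so that the register resolves
# against this hierarchy; the PTs themselves are synthetic content.

#' Synthetic term hierarchy
#'
#' Builds the packaged synthetic MedDRA-style hierarchy: 75 PTs under 23
#' HLTs, 13 HLGTs and 10 SOCs, with 10 SMQs. Grouping-term names match the
#' packaged historical-concern register (`uif_example("concerns.csv")`), so
#' the register's case definitions resolve against it. The same hierarchy
#' is shipped as a CSV bundle under `inst/extdata/synthetic_hierarchy/`.
#'
#' @return a `term_hierarchy`.
#' @export
make_synthetic_hierarchy <- function() {
  # pt, hlt, hlgt, soc, ime, dme, quality_issue
  def <- function(hlt, hlgt, soc, pts, ime = TRUE, dme = FALSE,
                  quality = FALSE) {
    data.frame(pt = pts, hlt = hlt, hlgt = hlgt, soc = soc,
               ime = ime, dme = dme, quality_issue = quality,
               stringsAsFactors = FALSE)
  }
  pt <- rbind(
    def("non-site specific embolism and thrombosis",
        "embolism and thrombosis", "vascular disorders",
        c("embolism venous", "thrombosis", "vascular occlusion")),
    def("site specific embolism and thrombosis",
        "embolism and thrombosis", "vascular disorders",
        c("deep vein thrombosis", "pulmonary embolism",
          "cerebral infarction", "portal vein thrombosis"),
        dme = c(FALSE, TRUE, FALSE, FALSE)),
    def("anaphylactic responses", "allergic conditions",
        "immune system disorders",
        c("anaphylactic reaction", "anaphylactic shock",
          "anaphylactoid reaction"),
        dme = c(TRUE, TRUE, FALSE)),
    def("allergic conditions nec", "allergic conditions",
        "immune system disorders",
        c("hypersensitivity", "drug hypersensitivity", "urticaria")),
    def("abdominal and gastrointestinal infections",
        "infections - pathogen unspecified", "infections and infestations",
        c("peritonitis", "gastroenteritis infectious",
          "abdominal infection")),
    def("peritoneal infections and febrile disorders",
        "infections - pathogen unspecified", "infections and infestations",
        c("peritonitis bacterial", "dialysis-related peritonitis",
          "febrile infection")),
    def("hyperglycaemic conditions",
        "glucose metabolism disorders (incl. diabetes mellitus)",
        "metabolism and nutrition disorders",
        c("hyperglycaemia", "diabetic ketoacidosis",
          "blood glucose increased")),
    def("hypoglycaemic conditions",
        "glucose metabolism disorders (incl. diabetes mellitus)",
        "metabolism and nutrition disorders",
        c("hypoglycaemia", "hypoglycaemic coma",
          "blood glucose decreased")),
    def("medication errors nec", "product use issues",
        "injury, poisoning and procedural complications",
        c("medication error", "incorrect dose administered",
          "drug administration error")),
    def("overdoses and underdoses", "product use issues",
        "injury, poisoning and procedural complications",
        c("overdose", "underdose", "accidental overdose")),
    def("product administration errors", "product use issues",
        "injury, poisoning and procedural complications",
        c("device use error", "wrong technique in product usage process",
          "product preparation error")),
    def("seizures", "neurological disorders nec",
        "nervous system disorders",
        c("seizure", "status epilepticus", "convulsion"),
        dme = c(FALSE, TRUE, FALSE)),
    def("disturbances in consciousness", "neurological disorders nec",
        "nervous system disorders",
        c("somnolence", "loss of consciousness", "lethargy")),
    def("substance-related disorders",
        "substance related and addictive disorders",
        "psychiatric disorders",
        c("drug abuse", "drug dependence", "drug withdrawal syndrome",
          "intentional product misuse")),
    def("psychotic disorders", "psychiatric disorders nec",
        "psychiatric disorders",
        c("psychotic disorder", "hallucination", "paranoia",
          "schizophrenia")),
    def("ventricular arrhythmias and cardiac arrest",
        "cardiac arrhythmias", "cardiac disorders",
        c("torsade de pointes", "electrocardiogram qt prolonged",
          "ventricular tachycardia", "cardiac arrest"),
        dme = c(TRUE, FALSE, FALSE, TRUE)),
    def("therapeutic responses decreased",
        "therapeutic and nontherapeutic responses",
        "general disorders and administration site conditions",
        c("drug ineffective", "therapeutic response decreased",
          "treatment failure")),
    def("product quality issues nec", "product quality issues",
        "general disorders and administration site conditions",
        c("product quality issue", "product contamination",
          "product label issue"),
        quality = TRUE),
    # background filler terms, mostly non-serious
    def("nausea and vomiting symptoms",
        "gastrointestinal signs and symptoms",
        "gastrointestinal disorders",
        c("nausea", "vomiting", "dyspepsia", "diarrhoea"),
        ime = FALSE),
    def("general signs and symptoms", "general system disorders",
        "general disorders and administration site conditions",
        c("fatigue", "pyrexia", "malaise", "oedema peripheral"),
        ime = c(FALSE, FALSE, FALSE, TRUE)),
    def("skin reactions nec", "epidermal and dermal conditions",
        "skin and subcutaneous tissue disorders",
        c("rash", "pruritus", "dermatitis", "toxic epidermal necrolysis"),
        ime = c(FALSE, FALSE, FALSE, TRUE),
        dme = c(FALSE, FALSE, FALSE, TRUE)),
    def("headaches and dizziness", "neurological signs and symptoms",
        "nervous system disorders",
        c("headache", "dizziness", "migraine"), ime = FALSE),
    def("respiratory signs and symptoms",
        "respiratory disorders nec",
        "respiratory, thoracic and mediastinal disorders",
        c("cough", "dyspnoea", "bronchospasm"),
        ime = c(FALSE, TRUE, TRUE))
  )

  smq <- function(id, narrow, broad_extra = character()) {
    rbind(
      data.frame(smq_id = id, pt = narrow, scope = "narrow",
                 stringsAsFactors = FALSE),
      if (length(broad_extra)) {
        data.frame(smq_id = id, pt = broad_extra, scope = "broad",
                   stringsAsFactors = FALSE)
      })
  }
  hlt_pts <- function(h) pt$pt[pt$hlt == h]
  hlgt_pts <- function(h) pt$pt[pt$hlgt == h]
  smq_tbl <- rbind(
    smq("embolic and thrombotic events",
        hlgt_pts("embolism and thrombosis")),
    smq("anaphylactic reactions", hlt_pts("anaphylactic responses"),
        c("hypersensitivity", "drug hypersensitivity", "urticaria",
          "bronchospasm")),
    smq("hypersensitivity", hlt_pts("allergic conditions nec"),
        c("anaphylactic reaction", "anaphylactoid reaction", "rash",
          "dermatitis")),
    smq("lack of efficacy/effect",
        hlt_pts("therapeutic responses decreased")),
    smq("hyperglycaemia/new onset diabetes mellitus",
        hlt_pts("hyperglycaemic conditions")),
    smq("hypoglycaemia", hlt_pts("hypoglycaemic conditions")),
    smq("medication errors", hlgt_pts("product use issues")),
    smq("drug abuse and dependence",
        hlt_pts("substance-related disorders")),
    smq("torsade de pointes/qt prolongation",
        c("torsade de pointes", "electrocardiogram qt prolonged",
          "ventricular tachycardia"),
        "cardiac arrest"),
    smq("psychosis and psychotic disorders",
        hlt_pts("psychotic disorders"))
  )
  term_hierarchy(pt, smq_tbl)
}

#' Path to a packaged example file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
uif_example <- function(file = NULL) {
  base <- system.file("extdata", package = "uifscan", mustWork = TRUE)
  if (is.null(file)) return(list.files(base, recursive = TRUE))
  path <- file.path(base, file)
  if (!file.exists(path)) stop("no packaged file ", file, call. = FALSE)
  path
}

#' The packaged 13-concern demo scenario
#'
#' A synthetic scenario mirroring the structure of the historical-concern
#' register shipped with the package: 13 substances, each with stationary
#' over-dispersed background reporting across 2007-01 to 2016-06 (~9.5
#' years), and one injected episode per concern — a 3-month elevation of
#' every PT under the concern's first grouping term, ending in the
#' concern's index month. Episode size is 6x the background mean per PT, a
#' spike of the order seen in historical contamination events.
#'
#' @param seed integer seed controlling the whole simulated database.
#' @param fold_increase episode height as a multiple of the background mean.
#' @param hierarchy a `term_hierarchy`; the default packaged hierarchy must
#'   be used for the packaged register to resolve.
#' @return a [sim_scenario()].
#' @export
default_scenario <- function(seed = 20080218L, fold_increase = 6,
                             hierarchy = make_synthetic_hierarchy()) {
  concerns <- load_concerns(uif_example("concerns.csv"), hierarchy)
  ids <- unique(concerns$concern_id)
  injections <- lapply(ids, function(id) {
    rows <- concerns[concerns$concern_id == id, , drop = FALSE]
    idx_month <- as_month(rows$index_date[1L])
    products <- concern_products(rows$product_names[1L])
    injection_spec(
      concern_id = id,
      substance = rows$substance[1L],
      product_name = if (length(products)) products[1L] else NA_character_,
      grouping_level = rows$grouping_level[1L],
      grouping_id = rows$grouping_id[1L],
      start_month = month_add(idx_month, -2L),
      duration_months = 3L,
      fold_increase = fold_increase,
      concern_type = rows$concern_type[1L],
      index_date = rows$index_date[1L])
  })
  sim_scenario(substances = unique(concerns$substance),
               pts_per_substance = 8L,
               baseline_mu = 2,
               dispersion_alpha = 0.3,
               trend_per_month = 1,
               literature_fraction = 0.1,
               months = c("2007-01", "2016-06"),
               injections = injections,
               seed = seed)
}
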
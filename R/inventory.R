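#' The 39-phoneme American English inventory
#'
#' Returns the phoneme inventory used throughout the package: 39
#' ARPAbet-style symbols (15 vowels, 24 consonants), each with a manner
#' class, voicing flag, sonority rank, a single-character alias (used by the
#' phoneme-string mode of [lev_ratio()]), a relative duration weight, and the
#' acoustic recipe consumed by [synthesize_token()] (formant frequencies for
#' sonorants, noise bands for fricatives, burst parameters for stops).
#'
#' Sonority ranks follow the sonority hierarchy: vowels (7) > glides (6) >
#' liquids (5) > nasals (4) > voiced fricatives (3) > voiceless fricatives =
#' voiced stops (2) > voiceless stops (1).
#'
#' @return A data frame with one row per phoneme and columns `phoneme`,
#'   `class` (one of `vowel`, `voiced_stop`, `voiceless_stop`, `fricative`,
#'   `affricate`, `nasal`, `liquid`, `glide`), `voiced`, `sonority`,
#'   `diphthong`, `char`, `durw`, and acoustic recipe columns (`f1`--`f3`,
#'   `f1e`--`f3e`, `noise_lo`, `noise_hi`, `burst_cf`, `amp`).
#' @examples
#' inv <- phoneme_inventory()
#' nrow(inv)         # 39
#' table(inv$class)
#' @export
phoneme_inventory <- function() {
  # phoneme, class, voiced, sonority, diphthong, durw, f1,f2,f3, f1e,f2e,f3e,
  # noise_lo, noise_hi, burst_cf, amp
  v <- function(p, son = 7L, d = FALSE, w = 1.6, f1, f2, f3 = 2500,
                f1e = NA, f2e = NA, f3e = NA)
    list(p, "vowel", TRUE, son, d, w, f1, f2, f3, f1e, f2e, f3e, NA, NA, NA, 1.0)
  rows <- list(
    v("IY", f1 = 270, f2 = 2290),
    v("IH", f1 = 390, f2 = 1990),
    v("EH", f1 = 530, f2 = 1840),
    v("AE", f1 = 660, f2 = 1720),
    v("AA", f1 = 730, f2 = 1090),
    v("AO", f1 = 570, f2 = 840),
    v("UH", f1 = 440, f2 = 1020),
    v("UW", f1 = 300, f2 = 870),
    v("AH", f1 = 640, f2 = 1190),
    v("ER", f1 = 490, f2 = 1350, f3 = 1690),
    v("EY", d = TRUE, w = 1.9, f1 = 480, f2 = 1880, f1e = 330, f2e = 2200),
    v("AY", d = TRUE, w = 1.9, f1 = 730, f2 = 1180, f1e = 330, f2e = 2100),
    v("AW", d = TRUE, w = 1.9, f1 = 730, f2 = 1180, f1e = 430, f2e = 980),
    v("OY", d = TRUE, w = 1.9, f1 = 560, f2 = 880, f1e = 350, f2e = 2000),
    v("OW", d = TRUE, w = 1.9, f1 = 550, f2 = 900, f1e = 320, f2e = 880),
    # glides / liquids: formant recipes, short
    list("W",  "glide",  TRUE, 6L, FALSE, 0.8, 300, 610, 2200, NA, NA, NA, NA, NA, NA, 0.7),
    list("Y",  "glide",  TRUE, 6L, FALSE, 0.8, 280, 2250, 3000, NA, NA, NA, NA, NA, NA, 0.7),
    list("L",  "liquid", TRUE, 5L, FALSE, 0.9, 360, 1300, 3000, NA, NA, NA, NA, NA, NA, 0.8),
    list("R",  "liquid", TRUE, 5L, FALSE, 0.9, 490, 1350, 1690, NA, NA, NA, NA, NA, NA, 0.8),
    # nasals: low murmur resonance + weak second formant
    list("M",  "nasal", TRUE, 4L, FALSE, 0.9, 250, 1000, 2200, NA, NA, NA, NA, NA, NA, 0.6),
    list("N",  "nasal", TRUE, 4L, FALSE, 0.9, 250, 1400, 2300, NA, NA, NA, NA, NA, NA, 0.6),
    list("NG", "nasal", TRUE, 4L, FALSE, 0.9, 250, 2000, 2600, NA, NA, NA, NA, NA, NA, 0.6),
    # fricatives: shaped noise bands (voiced ones mix in a voice source)
    list("F",  "fricative", FALSE, 2L, FALSE, 1.0, NA, NA, NA, NA, NA, NA, 1500, 7800, NA, 0.35),
    list("V",  "fricative", TRUE,  3L, FALSE, 0.9, NA, NA, NA, NA, NA, NA, 1500, 7800, NA, 0.35),
    list("TH", "fricative", FALSE, 2L, FALSE, 1.0, NA, NA, NA, NA, NA, NA, 1300, 7000, NA, 0.3),
    list("DH", "fricative", TRUE,  3L, FALSE, 0.9, NA, NA, NA, NA, NA, NA, 1300, 7000, NA, 0.3),
    list("S",  "fricative", FALSE, 2L, FALSE, 1.0, NA, NA, NA, NA, NA, NA, 4200, 8000, NA, 0.5),
    list("Z",  "fricative", TRUE,  3L, FALSE, 0.9, NA, NA, NA, NA, NA, NA, 4200, 8000, NA, 0.5),
    list("SH", "fricative", FALSE, 2L, FALSE, 1.0, NA, NA, NA, NA, NA, NA, 2300, 6500, NA, 0.5),
    list("ZH", "fricative", TRUE,  3L, FALSE, 0.9, NA, NA, NA, NA, NA, NA, 2300, 6500, NA, 0.5),
    list("HH", "fricative", FALSE, 2L, FALSE, 0.8, NA, NA, NA, NA, NA, NA, 500, 6000, NA, 0.25),
    # affricates: closure + frication burst (grouped with fricatives for the
    # 7-way onset task; see onset_class())
    list("CH", "affricate", FALSE, 1L, FALSE, 1.1, NA, NA, NA, NA, NA, NA, 2300, 6500, 2800, 0.5),
    list("JH", "affricate", TRUE,  2L, FALSE, 1.0, NA, NA, NA, NA, NA, NA, 2300, 6500, 2800, 0.5),
    # stops: closure silence + burst (voiced: voice bar + short VOT)
    list("P", "voiceless_stop", FALSE, 1L, FALSE, 0.9, NA, NA, NA, NA, NA, NA, NA, NA, 800,  0.8),
    list("B", "voiced_stop",    TRUE,  2L, FALSE, 0.8, NA, NA, NA, NA, NA, NA, NA, NA, 800,  0.8),
    list("T", "voiceless_stop", FALSE, 1L, FALSE, 0.9, NA, NA, NA, NA, NA, NA, NA, NA, 4000, 0.8),
    list("D", "voiced_stop",    TRUE,  2L, FALSE, 0.8, NA, NA, NA, NA, NA, NA, NA, NA, 4000, 0.8),
    list("K", "voiceless_stop", FALSE, 1L, FALSE, 0.9, NA, NA, NA, NA, NA, NA, NA, NA, 1800, 0.8),
    list("G", "voiced_stop",    TRUE,  2L, FALSE, 0.8, NA, NA, NA, NA, NA, NA, NA, NA, 1800, 0.8)
  )
  inv <- do.call(rbind, lapply(rows, function(r) {
    data.frame(phoneme = r[[1]], class = r[[2]], voiced = r[[3]],
               sonority = as.integer(r[[4]]), diphthong = r[[5]], durw = r[[6]],
               f1 = r[[7]], f2 = r[[8]], f3 = r[[9]],
               f1e = r[[10]], f2e = r[[11]], f3e = r[[12]],
               noise_lo = r[[13]], noise_hi = r[[14]], burst_cf = r[[15]],
               amp = r[[16]], stringsAsFactors = FALSE)
  }))
  inv$char <- c(letters, LETTERS)[seq_len(nrow(inv))]
  rownames(inv) <- inv$phoneme
  inv
}

#' Binary phonetic feature chart
#'
#' A 29-component binary feature vector per phoneme: 8 place + 7 manner +
#' voicing + syllabicity for consonants; 3 height + 3 backness + tenseness +
#' rounding + diphthong for vowels; 3 reserved (always-zero) components.
#' Every phoneme maps to a distinct vector; the slot encoder
#' ([encode_dorsal()]) only requires injectivity, not any particular feature
#' theory.
#'
#' @param inventory A phoneme inventory as returned by [phoneme_inventory()].
#' @return A binary integer matrix with 39 rows (phonemes) and 29 named
#'   feature columns.
#' @export
feature_chart <- function(inventory = phoneme_inventory()) {
  feats <- c(paste0("plc_", c("bilabial", "labiodental", "dental", "alveolar",
                              "postalveolar", "palatal", "velar", "glottal")),
             paste0("mnr_", c("stop", "fricative", "affricate", "nasal",
                              "lateral", "rhotic", "glide")),
             "voiced", "syllabic",
             paste0("hgt_", c("high", "mid", "low")),
             paste0("bck_", c("front", "central", "back")),
             "tense", "round", "diphthong",
             paste0("res", 1:3))
  stopifnot(length(feats) == 29L)
  m <- matrix(0L, nrow(inventory), length(feats),
              dimnames = list(inventory$phoneme, feats))
  vow <- list(  # height, backness, tense, round
    IY = c("high", "front", 1, 0),  IH = c("high", "front", 0, 0),
    EH = c("mid", "front", 0, 0),   AE = c("low", "front", 0, 0),
    AA = c("low", "back", 1, 0),    AO = c("mid", "back", 1, 1),
    UH = c("high", "back", 0, 1),   UW = c("high", "back", 1, 1),
    AH = c("mid", "central", 0, 0), ER = c("mid", "central", 1, 0),
    EY = c("mid", "front", 1, 0),   AY = c("low", "central", 0, 0),
    AW = c("low", "central", 0, 1), OY = c("mid", "back", 0, 1),
    OW = c("mid", "back", 1, 1))
  cons <- list(  # place, manner
    P = c("bilabial", "stop"),       B = c("bilabial", "stop"),
    T = c("alveolar", "stop"),       D = c("alveolar", "stop"),
    K = c("velar", "stop"),          G = c("velar", "stop"),
    CH = c("postalveolar", "affricate"), JH = c("postalveolar", "affricate"),
    F = c("labiodental", "fricative"),   V = c("labiodental", "fricative"),
    TH = c("dental", "fricative"),   DH = c("dental", "fricative"),
    S = c("alveolar", "fricative"),  Z = c("alveolar", "fricative"),
    SH = c("postalveolar", "fricative"), ZH = c("postalveolar", "fricative"),
    HH = c("glottal", "fricative"),
    M = c("bilabial", "nasal"),      N = c("alveolar", "nasal"),
    NG = c("velar", "nasal"),
    L = c("alveolar", "lateral"),    R = c("postalveolar", "rhotic"),
    W = c("bilabial", "glide"),      Y = c("palatal", "glide"))
  for (p in inventory$phoneme) {
    if (inventory[p, "class"] == "vowel") {
      f <- vow[[p]]
      m[p, paste0("hgt_", f[1])] <- 1L
      m[p, paste0("bck_", f[2])] <- 1L
      m[p, "tense"] <- as.integer(f[3])
      m[p, "round"] <- as.integer(f[4])
      m[p, "diphthong"] <- as.integer(inventory[p, "diphthong"])
      m[p, "syllabic"] <- 1L
      m[p, "voiced"] <- 1L
      if (p == "ER") m[p, "mnr_rhotic"] <- 1L  # rhotacized vowel
    } else {
      f <- cons[[p]]
      m[p, paste0("plc_", f[1])] <- 1L
      m[p, paste0("mnr_", f[2])] <- 1L
      m[p, "voiced"] <- as.integer(inventory[p, "voiced"])
    }
  }
  if (anyDuplicated(apply(m, 1, paste, collapse = "")))
    stop("feature chart is not injective")
  m
}

#' Map a word-initial phoneme to one of seven onset classes
#'
#' Onsets are classified by manner of articulation into vowels, voiced
#' stops, voiceless stops, fricatives, nasals, liquids, and glides.
#' Affricates are grouped with the fricatives: the seven-way scheme has no
#' affricate class and affricates pattern with the other obstruents.
#'
#' @param word A word entry (a row of a lexicon from [generate_lexicon()]),
#'   or a character vector of phonemes whose first element is the onset.
#' @param inventory The phoneme inventory.
#' @return A single string, one of `"vowel"`, `"voiced_stop"`,
#'   `"voiceless_stop"`, `"fricative"`, `"nasal"`, `"liquid"`, `"glide"`.
#' @export
onset_class <- function(word, inventory = phoneme_inventory()) {
  ph <- if (is.character(word)) word[1] else strsplit(word$phonemes, " ")[[1]][1]
  if (is.na(ph) || !ph %in% inventory$phoneme)
    stop("unknown phoneme symbol: ", ph)
  cls <- inventory[ph, "class"]
  if (cls == "affricate") "fricative" else cls
}

onset_classes <- function() {
  c("vowel", "voiced_stop", "voiceless_stop", "fricative", "nasal",
    "liquid", "glide")
}

# Legal syllable onsets (for the maximal-onset principle and for root
# generation). Singles: every consonant except NG. Clusters: obstruent +
# liquid/glide and s-clusters, the productive core of English onsets.
legal_onsets <- function(inventory = phoneme_inventory()) {
  singles <- inventory$phoneme[inventory$class != "vowel" &
                               inventory$phoneme != "NG"]
  doubles <- c("P R", "P L", "B R", "B L", "T R", "T W", "D R", "K R", "K L",
               "K W", "G R", "G L", "F R", "F L", "TH R", "SH R",
               "S P", "S T", "S K", "S M", "S N", "S L", "S W")
  triples <- c("S P R", "S P L", "S T R", "S K R", "S K W")
  c(singles, doubles, triples)
}
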
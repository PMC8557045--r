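#' @title Published reference tables for the CHD prescription corpus
#' @name chd_reference
#' @description
#' Summary tables published for a 715-case coronary-heart-disease (CHD)
#' prescription corpus of 182 herbs. The raw case records are not publicly
#' deposited, so these printed summaries are the only verifiable inputs:
#' the top-48 herb frequency table, the aggregated property/taste/meridian
#' occurrence counts, the seven frequent 5-herb combinations mined at
#' minimum support 0.3, and the 21 herbal-pair scores mined at minimum
#' support 0.6 on the 372-case qi-deficiency/blood-stasis subset. They are
#' used as worked-example inputs and to calibrate the synthetic generator.
NULL

#' Top-48 herb frequency table of the published CHD corpus
#'
#' @return a `"herb_frequency"` data.frame (48 rows, `n_cases = 715`) with
#'   percentages re-derived from the printed counts.
#' @export
chd_herb_frequency <- function() {
  herb <- c("Gan-cao", "Huang-qi", "Dang-gui", "Chuan-xiong", "Yan-hu-suo",
            "San-qi", "Mai-dong", "Dan-shen", "Ye-ge-gen", "Wu-wei-zi",
            "Huang-lian", "Bing-pian", "Suan-zao-ren", "Huang-qin",
            "Gui-zhi", "Gou-teng", "Fu-ling", "Ze-xie", "Shui-zhi",
            "Mu-xiang", "Bai-shao", "Ren-shen", "Yin-yang-huo", "Sheng-di",
            "Gua-lou", "Qing-hao", "Qiang-huo", "Sha-ren", "Dan-pi",
            "Chai-hu", "Huang-bo", "Rou-gui", "Zi-shi-ying", "Hou-pu",
            "He-shou-wu", "Shu-di", "Ye-jiao-teng", "Zhi-zi", "Xing-ren",
            "Zhi-qiao", "Ban-xia", "Jue-ming-zi", "Da-huang", "Xie-bai",
            "Fu-zi", "Bai-zhu", "Dang-shen", "Xi-xin")
  count <- c(543L, 536L, 525L, 509L, 483L, 444L, 423L, 417L, 372L, 361L,
             333L, 322L, 286L, 181L, 176L, 175L, 170L, 167L, 154L, 148L,
             140L, 119L, 110L, 105L, 102L, 101L, 101L, 94L, 93L, 92L, 90L,
             89L, 89L, 79L, 70L, 70L, 67L, 67L, 65L, 63L, 62L, 61L, 59L,
             58L, 56L, 56L, 53L, 51L)
  frequency_table(herb, count, n_cases = 715L)
}

#' Published property/taste/meridian occurrence counts of the CHD corpus
#'
#' Counts aggregate all 182 herbs over 10549 herb occurrences (the sum of
#' the property counts, each herb carrying exactly one property).
#'
#' @return named list with numeric vectors `properties`, `tastes`,
#'   `meridians` and the scalar `total_occurrences`.
#' @export
chd_attribute_counts <- function() {
  properties <- c(Warm = 4742, Cold = 3463, Mild = 1729, Cool = 440,
                  Hot = 175)
  tastes <- c(Sweet = 6134, Bitter = 5066, Pungent = 4234, Sour = 898,
              Mild = 369, Salty = 351, Puckery = 159)
  meridians <- c(Heart = 5987, Liver = 5236, Spleen = 4353, Lung = 3962,
                 Stomach = 3679, Kidney = 2037, `Large Intestine` = 1420,
                 Gallbladder = 1362, Bladder = 704, Pericardium = 684,
                 `Tri-jiao` = 108, `Small Intestine` = 35)
  list(properties = properties, tastes = tastes, meridians = meridians,
       total_occurrences = sum(properties))
}

#' Published frequent 5-herb combinations (deepest mined level)
#'
#' The seven frequent 5-itemsets mined from the CHD corpus at minimum
#' support 0.3, wrapped as a `"frequent_itemsets"` object whose single
#' populated level is level 5 — the input to [top_n_groups()].
#'
#' @return a `"frequent_itemsets"` object with levels 1-4 empty and level 5
#'   holding the seven printed itemsets (supports as printed).
#' @export
chd_l5_itemsets <- function() {
  sets <- list(
    list(c("Huang-qi", "Mai-dong", "San-qi", "Wu-wei-zi", "Yan-hu-suo"),
         0.33),
    list(c("Gan-cao", "Huang-qi", "Mai-dong", "San-qi", "Yan-hu-suo"),
         0.32),
    list(c("Gan-cao", "Huang-qi", "Mai-dong", "Wu-wei-zi", "Yan-hu-suo"),
         0.32),
    list(c("Gan-cao", "Huang-qi", "Mai-dong", "San-qi", "Wu-wei-zi"),
         0.32),
    list(c("Dang-gui", "Gan-cao", "Huang-qi", "Mai-dong", "Wu-wei-zi"),
         0.31),
    list(c("Dang-gui", "Gan-cao", "Huang-qi", "San-qi", "Yan-hu-suo"),
         0.30),
    list(c("Gan-cao", "Huang-qi", "San-qi", "Wu-wei-zi", "Yan-hu-suo"),
         0.30))
  items <- lapply(sets, function(s)
    list(herbs = sort_herbs(s[[1]]), support = s[[2]],
         count = as.integer(round(s[[2]] * 715))))
  levels <- c(rep(list(list()), 4L), list(sort_level(items)))
  new_frequent_itemsets(levels, min_support = 0.3, max_k = 5L,
                        n_cases = 715L)
}

#' Published herbal-pair scores of the qi-deficiency/blood-stasis subset
#'
#' The 21 pairs mined at minimum support 0.6 on the 372-case subset, as an
#' unranked (herb1, herb2, score) data.frame; rank with [pair_ranking()].
#'
#' @return data.frame with columns `herb1`, `herb2`, `score`.
#' @export
chd_pair_scores <- function() {
  data.frame(
    herb1 = c("Huang-qi", "Huang-qi", "Huang-qi", "Huang-qi", "Huang-qi",
              "Huang-qi", "Dang-gui", "Yan-hu-suo", "Huang-qi", "Gan-cao",
              "Huang-qi", "Dang-gui", "Dang-gui", "Mai-dong", "Dang-gui",
              "Gan-cao", "Gan-cao", "Gan-cao", "Dang-gui", "Mai-dong",
              "Dang-gui"),
    herb2 = c("Dang-gui", "Gan-cao", "Mai-dong", "Yan-hu-suo", "San-qi",
              "Dan-shen", "Gan-cao", "San-qi", "Chuan-xiong", "Mai-dong",
              "Wu-wei-zi", "Mai-dong", "Yan-hu-suo", "Wu-wei-zi", "San-qi",
              "Yan-hu-suo", "San-qi", "Dan-shen", "Dan-shen", "Yan-hu-suo",
              "Chuan-xiong"),
    score = c(0.85, 0.82, 0.75, 0.75, 0.74, 0.72, 0.72, 0.69, 0.67, 0.67,
              0.67, 0.66, 0.65, 0.65, 0.64, 0.64, 0.63, 0.62, 0.62, 0.61,
              0.60),
    stringsAsFactors = FALSE)
}
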
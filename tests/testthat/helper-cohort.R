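# Shared fixtures built in code

# vitals landing in every 2-point bin (SNS 14) / every 0-point bin (SNS 0)
best_vitals <- function() {
  list(resp_effort = "normal", heart_rate = 120, mean_bp = 45,
       temp_rectal = 37, crt_sec = 2, glucose_first = 80, spo2 = 98)
}
worst_vitals <- function() {
  list(resp_effort = "apnea_or_grunting", heart_rate = 60, mean_bp = 25,
       temp_rectal = 34, crt_sec = 7, glucose_first = 20, spo2 = 80)
}

# one complete cohort row; any field overridable
make_record <- function(..., id = "X1", ga_weeks = 38, bw_grams = 3000,
                        sex = "male", apgar1 = 8, place_of_birth = "level1",
                        at_hours = 4, eos = FALSE, died = FALSE,
                        followup_hours = 120, vitals = best_vitals()) {
  data.frame(id = id, ga_weeks = ga_weeks, bw_grams = bw_grams, sex = sex,
             apgar1 = apgar1, place_of_birth = place_of_birth,
             at_hours = at_hours, eos = eos,
             resp_effort = vitals$resp_effort, heart_rate = vitals$heart_rate,
             mean_bp = vitals$mean_bp, temp_rectal = vitals$temp_rectal,
             crt_sec = vitals$crt_sec, glucose_first = vitals$glucose_first,
             spo2 = vitals$spo2, died = died, followup_hours = followup_hours,
             ...)
}

# representative raw values for each component's scoring bins, most abnormal
# (0 points) first; used for monotonicity sweeps
bin_representatives <- function() {
  list(resp_effort = c("apnea_or_grunting", "tachypnea", "normal"),
       heart_rate = c(60, 180, 130),
       mean_bp = c(25, 35, 50),
       temp_rectal = c(34, 36.2, 37),
       crt_sec = c(8, 4, 2),
       glucose_first = c(20, 50, 90),
       spo2 = c(80, 88, 97))
}

# independent pair-counting AUC oracle: (concordant + half ties) / (n1 * n0)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# independent Breslow partial log-likelihood, direct per-event loop
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
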
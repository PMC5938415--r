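# Frozen published-table values used as oracles by the alignment and
# migration tests. Row order follows the printed tables.

published_fully_pw12 <- data.frame(
  z_mm = c(+5.20, +4.20, +3.20, +1.70, +1.20, -0.26, -8.30, -9.80),
  pw1 = c(4L, 6L, 8L, 11L, 13L, 18L, 51L, 57L),
  pw2 = c(4L, 6L, 8L, 11L, 13L, 18L, 53L, 59L),
  s = c(4L, 6L, 8L, 11L, 13L, 19L, 46L, 51L))

# the printed PW3 table also carries a '+0.00 11 11' row that is
# inconsistent with the source registry (PW3 11 is at +3.00 mm); the
# seven internally consistent rows are frozen here
published_fully_pw3 <- data.frame(
  z_mm = c(+4.20, +1.20, 0.00, -1.08, -4.20, -13.44, -14.16),
  pw3 = c(8L, 23L, 33L, 42L, 68L, 145L, 151L),
  s = c(6L, 13L, 17L, 23L, 33L, 67L, 70L))

published_narrow_pw12 <- data.frame(
  z_pw = c(+6.70, +2.20, +1.00, +0.48, -0.80, -1.30, -1.80, -2.80, -3.30, -4.16, -4.48, -5.20, -5.30, -5.60, -6.04, -6.80, -7.64, -8.80, -10.30, -10.80, -11.60, -11.80, -12.72, -13.24, -13.30, -13.80),
  pw1 = c(1L, 10L, 14L, 16L, 21L, 23L, 25L, 29L, 31L, 34L, 36L, 38L, 39L, 40L, 42L, 45L, 48L, 53L, 59L, 61L, 64L, 65L, 68L, 70L, 71L, 73L),
  pw2 = c(1L, 10L, 14L, 16L, 21L, 23L, 26L, 31L, 33L, 36L, 38L, 40L, 41L, 42L, 44L, 47L, 50L, 55L, 61L, 63L, 66L, 67L, 70L, 72L, 73L, 75L),
  z_s = c(+6.74, +2.15, +0.95, +0.45, -0.83, -1.33, -1.78, -2.85, -3.25, -4.20, -4.45, -5.25, -5.25, -5.65, -6.06, -6.85, -7.60, -8.85, -10.35, -10.85, -11.58, -11.75, -12.68, -13.28, -13.28, -13.76),
  s = c(2L, 10L, 14L, 15L, 22L, 24L, 26L, 29L, 30L, 33L, 34L, 37L, 37L, 38L, 39L, 42L, 44L, 48L, 53L, 55L, 58L, 59L, 63L, 66L, 66L, 69L),
  d_um = c(40L, 50L, 50L, 30L, 30L, 30L, 20L, 50L, 50L, 40L, 30L, 50L, 50L, 50L, 20L, 50L, 40L, 50L, 50L, 50L, 20L, 50L, 40L, 40L, 20L, 40L))

published_narrow_pw3 <- data.frame(
  pw3 = c(6L, 10L, 12L, 15L, 19L, 21L, 25L, 29L, 32L, 34L, 35L, 37L, 37L, 40L, 44L, 46L, 48L, 50L, 53L, 60L, 64L, 70L, 71L, 75L, 77L, 80L, 87L, 88L, 90L, 92L, 96L, 99L, 102L, 105L, 107L, 110L, 112L, 115L, 117L, 119L, 121L, 123L, 131L, 132L, 135L, 137L, 139L, 140L, 143L, 144L, 146L, 148L, 153L, 159L),
  s = c(4L, 8L, 9L, 10L, 11L, 12L, 14L, 15L, 16L, 18L, 19L, 20L, 21L, 22L, 24L, 25L, 26L, 27L, 28L, 30L, 31L, 34L, 35L, 36L, 37L, 38L, 40L, 41L, 42L, 43L, 44L, 45L, 46L, 47L, 48L, 49L, 50L, 51L, 52L, 53L, 54L, 55L, 59L, 60L, 61L, 62L, 63L, 64L, 65L, 66L, 68L, 69L, 71L, 73L),
  d_um = c(40L, 40L, 40L, 10L, 20L, 10L, 10L, 30L, 20L, 10L, 20L, 20L, 30L, 10L, 10L, 30L, 20L, 40L, 50L, 10L, 20L, 10L, 40L, 40L, 30L, 10L, 20L, 50L, 10L, 20L, 40L, 20L, 20L, 40L, 30L, 10L, 20L, 40L, 20L, 30L, 40L, 50L, 10L, 20L, 40L, 20L, 40L, 40L, 50L, 40L, 40L, 40L, 40L, 20L))

# printed per-row error columns of the migration table
published_migration_errors <- data.frame(
  pair = c("PW26>S26", "PW26>S26", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW31>S29", "PW33>S30", "PW33>S30", "PW33>S30", "PW33>S30"),
  case_label = c("00/115 (5b)", "00/123 (5b)", "99/153 (4)", "99/144 (4)", "99/152 (4)", "99/138 (4)", "00/049 (5a)", "00/036 (5a)", "99/151 (4)", "00/044 (5a)", "00/092 (*)", "00/039 (5a)", "99/143 (4)", "99/137 (4)", "00/057 (*)", "99/147 (4)", "00/084 (*)", "00/050 (5a)", "99/135 (4)", "00/086 (*)", "99/153 (4)", "99/144 (4)", "99/152 (4)", "99/138 (4)"),
  tag = c("a", "b", "a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l", "m", "n", "o", "p", "q", "r", "a", "b", "c", "d"),
  ab_x = c(0.0032, 0.0032, 0.08472, 0.00808, 0.00444, 0.00804, 0.00804, 0.00804, 0.04028, 0.02416, 0.02416, 0.06184, 0.23368, 0.23368, 0.20236, 0.1692, 0.16916, 0.1692, 0.1692, 0.1692, 0.00748, 0.0088, 0.00864, 0.00832),
  ab_y = c(0.2366, 0.45768, 0.57776, 0.67588, 0.67584, 0.67584, 0.67584, 0.67584, 0.57912, 0.54692, 0.54692, 0.5366, 0.32132, 0.32132, 0.299, 0.32128, 0.32132, 0.32128, 0.32128, 0.32132, 0.30104, 0.30016, 0.29904, 0.29896),
  ab = c(0.236622, 0.457691, 0.583938, 0.675928, 0.675855, 0.675888, 0.675888, 0.675888, 0.580519, 0.547453, 0.547453, 0.540152, 0.397307, 0.397307, 0.361041, 0.363111, 0.363128, 0.363111, 0.363111, 0.363146, 0.301133, 0.300289, 0.299165, 0.299076),
  phi_deg = c(89.225, 89.599, 81.658, 89.315, 89.624, 89.318, 89.318, 89.318, 86.021, 87.471, 87.471, 83.426, 53.973, 53.973, 55.91, 62.227, 62.235, 62.227, 62.227, 62.23, 88.577, 88.321, 88.345, 88.406))

published_migration_mean <- c(Ax = -0.00668, Ay = -0.16578, Bx = 0.06363, By = -0.60778, ABx = 0.07613, ABy = 0.44201, AB = 0.460175, phi = 78.351)
# the printed SEM row equals sample SD / sqrt(26) although n = 24
published_migration_sem <- c(Ax = 0.03564, Ay = 0.06012, Bx = 0.04593, By = 0.04195, ABx = 0.01679, ABy = 0.03134, AB = 0.028963, phi = 2.747)
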
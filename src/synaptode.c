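/* Compiled right-hand side of the 7-variable synaptic transmission model,
 * in the deSolve compiled-model interface. States:
 *   y[0] U       somatic potential, mV (held constant under voltage clamp)
 *   y[1] U_d     dendritic potential, mV (inactive in 1-compartment mode)
 *   y[2] m_AMPA  AMPA gating fraction
 *   y[3] C_glu   cleft glutamate, uM
 *   y[4] C_per   perisynaptic glutamate, uM
 *   y[5] F       facilitation fraction
 *   y[6] D       desensitization fraction
 * The release flux is piecewise constant; the integrator is restarted at
 * every pulse edge, so nu enters as the constant parameter NU_NOW.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 31
static double parms[N_PARMS];

#define TAU_M     parms[0]
#define GAMMA     parms[1]
#define ELL       parms[2]
#define G_S       parms[3]
#define U_L       parms[4]
#define GBAR_A    parms[5]
#define GBAR_N    parms[6]
#define U_A_REV   parms[7]
#define U_N_REV   parms[8]
#define MG_OUT    parms[9]
#define TAU_A     parms[10]
#define EC50_A    parms[11]
#define HILL_A    parms[12]
#define EC50_N    parms[13]
#define TAU_GLU   parms[14]
#define TAU_DIFF  parms[15]
#define BETA      parms[16]
#define C0        parms[17]
#define ALPHA_EFF parms[18]  /* alpha_periph * sodium factor; 0 = blockade */
#define K_HALF    parms[19]
#define TAU_F     parms[20]
#define H_F       parms[21]
#define F0        parms[22]
#define TAU_D     parms[23]
#define H_D       parms[24]
#define NU_NOW    parms[25]  /* release flux in the current segment, uM/ms */
#define MODE      parms[26]  /* 0 cc 2-comp, 1 vc 2-comp, 2 cc 1-comp, 3 vc 1-comp */
#define V_H       parms[27]
#define I_INJ     parms[28]
#define DRIVE_SOMA parms[29] /* 1: driving force read at soma (literal form) */
#define QSS_F     parms[30]  /* 1: facilitation at quasi-steady state (6-ODE) */

void synaptode_init(void (*odeparms)(int *, double *))
{
  int n = N_PARMS;
  odeparms(&n, parms);
}

static double s_ampa_c(double c)
{
  if (c <= 0.0) return 0.0;
  return 1.0 / (1.0 + pow(EC50_A / c, HILL_A));
}

static double s_nmda_c(double c)
{
  if (c <= 0.0) return 0.0;
  return c / (c + EC50_N);
}

void synaptode_deriv(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
  double U = y[0], Ud = y[1], mA = y[2], Cg = y[3], Cp = y[4],
         F = y[5], D = y[6];
  double Cgc = Cg > 0.0 ? Cg : 0.0;   /* clip for nonlinear terms only */
  double Cpc = Cp > 0.0 ? Cp : 0.0;
  int mode = (int) MODE;
  int onecomp = mode >= 2;
  int clamped = (mode == 1 || mode == 3);

  double sA = s_ampa_c(Cgc);
  double mN = s_nmda_c(Cpc) - s_nmda_c(C0);
  if (mN < 0.0) mN = 0.0;

  double x = TAU_F * H_F * Cpc / K_HALF;
  double Feff = QSS_F > 0.5 ? (F0 + x) / (1.0 + x) : F;

  double Usoma = clamped ? V_H : U;
  double Vmg = onecomp ? Usoma : Ud;
  double Vdrive = (onecomp || DRIVE_SOMA > 0.5) ? Usoma : Ud;

  double fmg = 1.0 / (1.0 + (MG_OUT / 3.57) * exp(-0.062 * Vmg));
  double IA = GBAR_A * mA * (U_A_REV - Vdrive);
  double IN = GBAR_N * mN * fmg * (U_N_REV - Vdrive);
  double Id = IA + IN;

  if (onecomp) {
    ydot[0] = clamped ? 0.0
      : (-(U - U_L) + (IA + IN + I_INJ) / G_S) / TAU_M;
    ydot[1] = 0.0;
  } else if (clamped) {
    ydot[0] = 0.0;
    ydot[1] = (-(Ud - U_L) - (2.0 / ELL) * (Ud - V_H)
               + Id / (GAMMA * G_S)) / TAU_M;
  } else {
    ydot[0] = (-(U - U_L) + (2.0 * GAMMA / ELL) * (Ud - U)
               + I_INJ / G_S) / TAU_M;
    ydot[1] = (-(Ud - U_L) - (2.0 / ELL) * (Ud - U)
               + Id / (GAMMA * G_S)) / TAU_M;
  }

  ydot[2] = (sA * D - mA) / TAU_A;
  ydot[3] = (Cp - Cg) / TAU_GLU + Feff * NU_NOW;
  ydot[4] = (Cg - Cp) / (BETA * TAU_GLU) - (Cp - C0) / TAU_DIFF
            - ALPHA_EFF * Cpc / (K_HALF + Cpc);
  ydot[5] = QSS_F > 0.5 ? 0.0
    : (F0 - F) / TAU_F + H_F * (1.0 - F) * Cpc / K_HALF;
  ydot[6] = (1.0 - D) / TAU_D - H_D * D * sA;
}
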
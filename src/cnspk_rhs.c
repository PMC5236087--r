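/* Mass-balance right-hand side for the multi-compartmental CNS model.
 *
 * State (amounts, ng):
 *   y[0] plasma, y[1] per1, y[2] per2, y[3] brain_ecf, y[4] brain_icf,
 *   y[5] csf_lv, y[6] csf_tfv, y[7] csf_cm, y[8] csf_sas, y[9] csf_evd
 *
 * Disabled compartments carry zero flows and a placeholder unit volume so
 * the state layout is fixed; their amounts stay identically zero.
 */
#include <R.h>

static double parms[20];

#define CL_PL    parms[0]   /* effective plasma clearance, mL/min   */
#define Q_PER1   parms[1]
#define Q_PER2   parms[2]
#define Q_ECF    parms[3]   /* BBB transfer clearance Q_PL_ECF      */
#define Q_LVPL   parms[4]   /* BCSFB efflux, LV -> plasma           */
#define Q_ECFICF parms[5]
#define Q_DIFF   parms[6]   /* single drug dispersion flow          */
#define Q_EVD    parms[7]   /* EVD drainage, LV -> EVD reservoir    */
#define FP       parms[8]   /* unbound fraction in plasma           */
#define V_PL     parms[9]
#define V_PER1   parms[10]
#define V_PER2   parms[11]
#define V_ECF    parms[12]
#define V_ICF    parms[13]
#define V_LV     parms[14]
#define V_TFV    parms[15]
#define V_CM     parms[16]
#define V_SAS    parms[17]
#define V_EVD    parms[18]
#define RATE     parms[19]  /* current infusion rate, ng/min        */

void cnspk_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms);
}

void cnspk_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double c_pl  = y[0] / V_PL;
    double c_p1  = y[1] / V_PER1;
    double c_p2  = y[2] / V_PER2;
    double c_ecf = y[3] / V_ECF;
    double c_icf = y[4] / V_ICF;
    double c_lv  = y[5] / V_LV;
    double c_tfv = y[6] / V_TFV;
    double c_cm  = y[7] / V_CM;
    double c_sas = y[8] / V_SAS;
    double c_evd = y[9] / V_EVD;

    double j_bbb = Q_ECF * (FP * c_pl - c_ecf);      /* plasma -> ECF  */
    double j_icf = Q_ECFICF * (c_ecf - c_icf);       /* ECF -> ICF     */

    ydot[0] = RATE
        + Q_PER1 * (c_p1 - c_pl)
        + Q_PER2 * (c_p2 - c_pl)
        - CL_PL * c_pl
        - j_bbb
        + Q_DIFF * c_sas          /* CSF reabsorption from SAS        */
        + Q_LVPL * c_lv;          /* BCSFB efflux return              */
    ydot[1] = Q_PER1 * (c_pl - c_p1);
    ydot[2] = Q_PER2 * (c_pl - c_p2);
    ydot[3] = j_bbb - Q_DIFF * c_ecf - j_icf;
    ydot[4] = j_icf;
    ydot[5] = Q_DIFF * c_ecf - Q_DIFF * c_lv - Q_LVPL * c_lv - Q_EVD * c_lv;
    ydot[6] = Q_DIFF * (c_lv - c_tfv);
    ydot[7] = Q_DIFF * (c_tfv - c_cm);
    ydot[8] = Q_DIFF * (c_cm - c_sas);
    ydot[9] = Q_EVD * (c_lv - c_evd);  /* reservoir drained externally */
}
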
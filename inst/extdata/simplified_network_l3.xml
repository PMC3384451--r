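<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="simplified_network" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="pyr" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="atp" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="nadh" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="ac" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="waste" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="co2" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="o2" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
      <parameter id="lb_glc" value="-10" constant="true"/>
      <parameter id="lb_big" value="-1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_glycolysis" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pyr" stoichiometry="2" constant="true"/>
          <speciesReference species="atp" stoichiometry="2" constant="true"/>
          <speciesReference species="nadh" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_acetate" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="pyr" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="ac" stoichiometry="1" constant="true"/>
          <speciesReference species="co2" stoichiometry="1" constant="true"/>
          <speciesReference species="atp" stoichiometry="1" constant="true"/>
          <speciesReference species="nadh" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_lactate" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="pyr" stoichiometry="1" constant="true"/>
          <speciesReference species="nadh" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="waste" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_tca" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="pyr" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="co2" stoichiometry="3" constant="true"/>
          <speciesReference species="nadh" stoichiometry="5" constant="true"/>
          <speciesReference species="atp" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_oxphos" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="nadh" stoichiometry="1" constant="true"/>
          <speciesReference species="o2" stoichiometry="0.5" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="atp" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_glc" reversible="true" fast="false" fbc:lowerFluxBound="lb_glc" fbc:upperFluxBound="lb_zero">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_o2" reversible="true" fast="false" fbc:lowerFluxBound="lb_big" fbc:upperFluxBound="lb_zero">
        <listOfReactants>
          <speciesReference species="o2" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_ac" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="ac" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_waste" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="waste" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_co2" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="co2" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="DM_atp" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="atp" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="DM_atp" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
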